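## Heavy-atom least-squares RMSD and its symmetry-corrected variant --------

#' Minimum heavy-atom RMSD after least-squares superposition
#'
#' Minimises over all rigid superpositions (proper rotation + translation;
#' reflections are excluded because mirror images are distinct conformers)
#' of the heavy-atom subsets.
#'
#' @param coordsA,coordsB full coordinate matrices (atoms x 3).
#' @param heavyIdx indices of the heavy atoms (applied to both sets); use
#'   `NULL` to superpose all rows.
#' @return RMSD in Angstrom.
#' @export
alignedRmsd <- function(coordsA, coordsB, heavyIdx = NULL) {
  if (!is.null(heavyIdx)) {
    coordsA <- coordsA[heavyIdx, , drop = FALSE]
    coordsB <- coordsB[heavyIdx, , drop = FALSE]
  }
  if (nrow(coordsA) != nrow(coordsB)) {
    stop("mismatched atom counts: ", nrow(coordsA), " vs ", nrow(coordsB))
  }
  kabsch_rmsd_cpp(coordsA, coordsB)
}

#' Symmetry-corrected heavy-atom RMSD
#'
#' Iterates over the molecule's graph automorphisms, computes the aligned
#' heavy-atom RMSD of A against the permuted B for each, and takes the
#' minimum. This removes the overestimation caused by topologically
#' equivalent atoms (e.g. a para-substituted phenyl ring rotated by 180
#' degrees should read 0).
#'
#' @param mol A [MoleculeGraph-class].
#' @param confA,confB [ConformerRecord-class] objects (or coordinate
#'   matrices) of the same molecule.
#' @param autos An [AutomorphismSet-class]; defaults to enumerating it.
#' @return list with `rmsd` (Angstrom) and `bestAutomorphism` (integer
#'   permutation of heavy positions; identity when no permutation helps).
#' @export
symmetryCorrectedRmsd <- function(mol, confA, confB,
                                  autos = enumerateAutomorphisms(mol)) {
  A <- if (is(confA, "ConformerRecord")) confCoords(confA) else confA
  B <- if (is(confB, "ConformerRecord")) confCoords(confB) else confB
  heavy <- mol@heavyIdx
  Ah <- A[heavy, , drop = FALSE]
  Bh <- B[heavy, , drop = FALSE]
  best <- Inf
  bestPerm <- seq_along(heavy)
  for (p in autos@perms) {
    r <- kabsch_rmsd_cpp(Ah, Bh[p, , drop = FALSE])
    if (r < best) { best <- r; bestPerm <- p }
  }
  list(rmsd = best, bestAutomorphism = bestPerm)
}

# Plain heavy-atom RMSD closure for a molecule (used by the diversity tree).
.heavyRmsdFun <- function(mol) {
  heavy <- mol@heavyIdx
  function(ha, hb) kabsch_rmsd_cpp(ha, hb)
}
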