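## Crystal-recovery benchmark ----------------------------------------------

# Same heavy-atom graph? (element sequence + heavy bond multiset)
.sameHeavyGraph <- function(molA, molB) {
  ga <- .heavyGraph(molA); gb <- .heavyGraph(molB)
  if (ga$n != gb$n) return(FALSE)
  if (!identical(ga$element, gb$element)) return(FALSE)
  key <- function(g) {
    if (nrow(g$edges) == 0) return(character(0))
    sort(sprintf("%d-%d:%.1f", pmin(g$edges[, 1], g$edges[, 2]),
                 pmax(g$edges[, 1], g$edges[, 2]), g$order))
  }
  identical(key(ga), key(gb))
}

#' Minimum symmetry-corrected RMSD of an ensemble to a reference conformer
#'
#' @param mol A [MoleculeGraph-class] (shared by ensemble and reference).
#' @param ensemble list of [ConformerRecord-class].
#' @param referenceConf the reference (crystal) [ConformerRecord-class].
#' @param refMol optional [MoleculeGraph-class] of the reference record,
#'   checked to have the same heavy-atom graph.
#' @param autos optional precomputed [AutomorphismSet-class].
#' @return minimum RMSD in Angstrom.
#' @export
minRmsdToReference <- function(mol, ensemble, referenceConf, refMol = NULL,
                               autos = enumerateAutomorphisms(mol)) {
  if (length(ensemble) == 0) stop("ensemble must be non-empty")
  if (!is.null(refMol) && !.sameHeavyGraph(mol, refMol)) {
    stop("reference molecule '", molTitle(refMol),
         "' does not share the heavy-atom graph of '", molTitle(mol), "'")
  }
  min(vapply(ensemble, function(cf) {
    symmetryCorrectedRmsd(mol, cf, referenceConf, autos)$rmsd
  }, numeric(1)))
}

#' Percent recovery at an RMSD cutoff
#'
#' The percentage of molecules with at least one generated conformer within
#' `cutoff` of the reference structure.
#'
#' @param minRmsds numeric vector of per-molecule minimum RMSDs (Angstrom).
#' @param cutoff RMSD cutoff in Angstrom.
#' @return percent in \[0, 100\] (raw; round for presentation).
#' @export
percentRecovery <- function(minRmsds, cutoff) {
  if (length(minRmsds) == 0) stop("minRmsds must be non-empty")
  100 * sum(minRmsds <= cutoff) / length(minRmsds)
}

#' Build a recovery report for a set of molecules
#'
#' @param perMolecule data.frame with at least `title`, `rotatableBonds`,
#'   `totalConformers`, `tested`, `lowEnergy`, `diverse`, `minRmsd`.
#' @param cutoffs RMSD cutoffs (default 1.0, 1.5, 2.0 Angstrom).
#' @return A [RecoveryReport-class].
#' @export
recoveryReport <- function(perMolecule, cutoffs = c(1.0, 1.5, 2.0)) {
  rec <- vapply(cutoffs, function(cu) percentRecovery(perMolecule$minRmsd, cu),
                numeric(1))
  new("RecoveryReport", perMolecule = perMolecule,
      cutoffs = cutoffs, recovery = rec)
}

#' Ensemble statistics grouped by rotatable-bond count
#'
#' Medians of the conformer counts (index-space size, tested, low-energy,
#' diverse) and of the minimum RMSD to the reference, per rotatable-bond
#' count. Conformer totals are the post-symmetry-reduction index-space
#' sizes.
#'
#' @param report A [RecoveryReport-class] (or its `perMolecule` data.frame).
#' @return data.frame, one row per rotatable-bond count.
#' @export
ensembleStatistics <- function(report) {
  pm <- if (is(report, "RecoveryReport")) report@perMolecule else report
  if (nrow(pm) == 0) stop("need at least one molecule")
  split_ <- split(pm, pm$rotatableBonds)
  out <- do.call(rbind, lapply(split_, function(g) {
    data.frame(
      rotatableBonds = g$rotatableBonds[1],
      molecules = nrow(g),
      totalConformers = median(g$totalConformers),
      lowEnergyConformers = median(g$lowEnergy),
      diverseConformers = median(g$diverse),
      minRmsdMedian = median(g$minRmsd)
    )
  }))
  rownames(out) <- NULL
  out[order(out$rotatableBonds), , drop = FALSE]
}
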