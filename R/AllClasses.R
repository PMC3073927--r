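#' @include confabR-package.R
NULL

## ---------------------------------------------------------------------------
## MoleculeGraph
## ---------------------------------------------------------------------------

#' Molecular graph with perceived atom properties
#'
#' Holds one molecule as an attributed graph: per-atom element symbol, formal
#' charge, ring membership and hybridisation, and per-bond order, ring and
#' aromatic flags. Atom indices are 1-based and contiguous; hydrogens are
#' retained. `heavyIdx` lists the non-hydrogen atoms in input order --
#' RMSD, symmetry classes and automorphisms all operate on this subset.
#'
#' @slot atoms data.frame with columns `element` (character), `charge`
#'   (integer), `inRing` (logical), `hybrid` (character, one of
#'   `"sp"`, `"sp2"`, `"sp3"`, `"other"`).
#' @slot bonds data.frame with columns `i`, `j` (integer atom indices),
#'   `order` (integer 1/2/3), `aromatic` (logical), `inRing` (logical).
#' @slot title character molecule title from the input record.
#' @slot heavyIdx integer indices of the non-hydrogen atoms, in input order.
#'
#' @exportClass MoleculeGraph
setClass("MoleculeGraph",
  slots = c(
    atoms = "data.frame",
    bonds = "data.frame",
    title = "character",
    heavyIdx = "integer"
  )
)

setValidity("MoleculeGraph", function(object) {
  a <- object@atoms
  b <- object@bonds
  msg <- character()
  need <- c("element", "charge", "inRing", "hybrid")
  if (!all(need %in% names(a))) {
    msg <- c(msg, "atoms must have columns element, charge, inRing, hybrid")
  }
  if (nrow(b) > 0) {
    if (!all(c("i", "j", "order", "aromatic", "inRing") %in% names(b))) {
      msg <- c(msg, "bonds must have columns i, j, order, aromatic, inRing")
    } else {
      if (any(b$i == b$j)) msg <- c(msg, "bond references identical atoms")
      if (any(b$i < 1 | b$i > nrow(a) | b$j < 1 | b$j > nrow(a))) {
        msg <- c(msg, "bond references a non-existent atom")
      }
      if (!all(b$order %in% 1:3)) msg <- c(msg, "bond order must be 1, 2 or 3")
    }
  }
  if (length(msg) == 0 && nrow(a) > 0) {
    expected <- which(a$element != "H")
    if (!identical(as.integer(object@heavyIdx), as.integer(expected))) {
      msg <- c(msg, "heavyIdx must list exactly the non-hydrogen atoms in input order")
    }
    if (!all(a$hybrid %in% c("sp", "sp2", "sp3", "other"))) {
      msg <- c(msg, "hybrid must be sp, sp2, sp3 or other")
    }
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn MoleculeGraph-class Number of atoms (hydrogens included).
#' @param mol A `MoleculeGraph`.
#' @export
atomCount <- function(mol) nrow(mol@atoms)

#' @describeIn MoleculeGraph-class Indices of the non-hydrogen atoms.
#' @export
heavyAtoms <- function(mol) mol@heavyIdx

#' @describeIn MoleculeGraph-class Molecule title.
#' @export
molTitle <- function(mol) mol@title

setMethod("show", "MoleculeGraph", function(object) {
  cat(sprintf(
    "MoleculeGraph '%s': %d atoms (%d heavy), %d bonds, %d ring atoms\n",
    object@title, nrow(object@atoms), length(object@heavyIdx),
    nrow(object@bonds), sum(object@atoms$inRing)
  ))
})

## ---------------------------------------------------------------------------
## ConformerRecord
## ---------------------------------------------------------------------------

#' One conformer: coordinates, relative energy and conformer index
#'
#' @slot coords numeric matrix (atoms x 3), Angstrom, rows aligned with the
#'   parent [MoleculeGraph-class] atom indices.
#' @slot relEnergy numeric, kcal/mol relative to the current energy reference
#'   (the lowest-energy conformer found); non-negative once the reference is
#'   final.
#' @slot index numeric, non-negative whole conformer index in the mixed-radix
#'   torsion space (stored as double so index spaces beyond 2^31 work).
#'
#' @exportClass ConformerRecord
setClass("ConformerRecord",
  slots = c(coords = "matrix", relEnergy = "numeric", index = "numeric")
)

setValidity("ConformerRecord", function(object) {
  msg <- character()
  if (ncol(object@coords) != 3) msg <- c(msg, "coords must have 3 columns")
  if (!is.numeric(object@coords)) msg <- c(msg, "coords must be numeric")
  if (length(object@index) != 1 || object@index < 0 ||
      object@index != floor(object@index)) {
    msg <- c(msg, "index must be a single non-negative whole number")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a ConformerRecord
#'
#' @param coords numeric matrix (atoms x 3) of Angstrom coordinates.
#' @param relEnergy relative energy in kcal/mol.
#' @param index conformer index (non-negative whole number).
#' @return A [ConformerRecord-class].
#' @export
ConformerRecord <- function(coords, relEnergy = 0, index = 0) {
  new("ConformerRecord", coords = unname(as.matrix(coords)),
      relEnergy = as.numeric(relEnergy), index = as.numeric(index))
}

#' @describeIn ConformerRecord-class Coordinates matrix.
#' @param conf A `ConformerRecord`.
#' @export
confCoords <- function(conf) conf@coords

#' @describeIn ConformerRecord-class Relative energy (kcal/mol).
#' @export
relEnergy <- function(conf) conf@relEnergy

#' @describeIn ConformerRecord-class Conformer index.
#' @export
confIndex <- function(conf) conf@index

setMethod("show", "ConformerRecord", function(object) {
  cat(sprintf("ConformerRecord: %d atoms, index %s, rel. energy %.4f kcal/mol\n",
              nrow(object@coords), format(object@index, scientific = FALSE),
              object@relEnergy))
})

## ---------------------------------------------------------------------------
## SymmetryClasses / AutomorphismSet
## ---------------------------------------------------------------------------

#' Topological symmetry classes of the heavy atoms
#'
#' Result of iterative (Morgan-style) refinement on the heavy-atom graph.
#' `classId[k]` is the class of heavy atom `heavyIdx[k]`; ids are canonical
#' (assigned by sorted invariant signature) so isomorphic graphs get identical
#' class multisets.
#'
#' @slot classId integer vector, one entry per heavy atom.
#' @slot heavyIdx integer, the heavy-atom indices the classes refer to.
#' @exportClass SymmetryClasses
setClass("SymmetryClasses",
  slots = c(classId = "integer", heavyIdx = "integer")
)

setValidity("SymmetryClasses", function(object) {
  if (length(object@classId) != length(object@heavyIdx)) {
    "classId and heavyIdx must have equal length"
  } else TRUE
})

setMethod("show", "SymmetryClasses", function(object) {
  cat(sprintf("SymmetryClasses: %d heavy atoms in %d classes\n",
              length(object@classId), length(unique(object@classId))))
})

#' Graph automorphisms of the heavy-atom graph
#'
#' Each permutation maps positions in the heavy-atom list onto positions and
#' preserves element, formal charge and bond orders. The identity is always
#' present. When enumeration was stopped at the cap, `truncated` is `TRUE`
#' and the set may not be closed under composition.
#'
#' @slot perms list of integer permutations of `seq_along(heavyIdx)`.
#' @slot heavyIdx integer heavy-atom indices.
#' @slot truncated logical, `TRUE` if the enumeration cap was hit.
#' @exportClass AutomorphismSet
setClass("AutomorphismSet",
  slots = c(perms = "list", heavyIdx = "integer", truncated = "logical")
)

setValidity("AutomorphismSet", function(object) {
  n <- length(object@heavyIdx)
  ok <- vapply(object@perms, function(p) {
    length(p) == n && all(sort(as.integer(p)) == seq_len(n))
  }, logical(1))
  if (length(object@perms) == 0) return("at least the identity must be present")
  if (!all(ok)) return("each element must be a permutation of the heavy atoms")
  has_id <- any(vapply(object@perms, function(p) all(p == seq_len(n)), logical(1)))
  if (!has_id) return("identity permutation must be present")
  TRUE
})

setMethod("show", "AutomorphismSet", function(object) {
  cat(sprintf("AutomorphismSet: %d automorphism(s) on %d heavy atoms%s\n",
              length(object@perms), length(object@heavyIdx),
              if (object@truncated) " (truncated)" else ""))
})

## ---------------------------------------------------------------------------
## Torsion library / rotors
## ---------------------------------------------------------------------------

#' A SMARTS-keyed torsion-angle library
#'
#' Plain-text format, one rule per line: a 4-atom SMARTS pattern followed by
#' whitespace-separated allowed angles in degrees; `#` starts a comment. The
#' driven bond is the pattern's 2nd-3rd atom pair, and the first matching
#' rule in file order wins.
#'
#' @slot rules data.frame with columns `smarts` (character), `angles`
#'   (list of numeric vectors, each sorted, unique, in \[0, 360)), `priority`
#'   (integer line order).
#' @exportClass TorsionLibrary
setClass("TorsionLibrary", slots = c(rules = "data.frame"))

setValidity("TorsionLibrary", function(object) {
  r <- object@rules
  if (!all(c("smarts", "angles", "priority") %in% names(r))) {
    return("rules must have columns smarts, angles, priority")
  }
  for (a in r$angles) {
    if (length(a) == 0) return("each rule must have at least one angle")
    if (any(a < 0 | a >= 360)) return("angles must lie in [0, 360)")
    if (is.unsorted(a, strictly = TRUE)) return("angles must be sorted and unique")
  }
  TRUE
})

setMethod("show", "TorsionLibrary", function(object) {
  cat(sprintf("TorsionLibrary: %d rule(s)\n", nrow(object@rules)))
})

#' The rotatable bonds of a molecule and their allowed torsion angles
#'
#' Rotors are ordered most-central-first (bond eccentricity on the heavy-atom
#' graph, ties by discovery order). Each rotor carries the driven bond, a
#' deterministic reference quadruple, the allowed angles after symmetry-fold
#' reduction, the fold, and the set of atoms moved by the rotation. The
#' conformer index space is the mixed-radix product of the per-rotor angle
#' counts (rotor 1 least significant).
#'
#' @slot rotors list; each element has fields `bond` (integer b, c), `quad`
#'   (integer a, b, c, d), `angles` (numeric degrees), `fold` (integer),
#'   `moving` (integer atom indices rotated with the torsion).
#' @slot totalConformers numeric, product of the per-rotor angle counts.
#' @exportClass RotorSet
setClass("RotorSet",
  slots = c(rotors = "list", totalConformers = "numeric")
)

setValidity("RotorSet", function(object) {
  for (r in object@rotors) {
    if (!all(c("bond", "quad", "angles", "fold", "moving") %in% names(r))) {
      return("each rotor needs bond, quad, angles, fold, moving")
    }
    if (length(r$angles) == 0) return("rotor has empty angle set")
    if (!r$fold %in% c(1L, 2L, 3L, 4L, 6L)) return("fold must be 1, 2, 3, 4 or 6")
    if (any(r$bond %in% r$moving)) return("moving fragment must exclude the bond atoms")
  }
  tot <- prod(vapply(object@rotors, function(r) length(r$angles), numeric(1)))
  if (length(object@rotors) > 0 && !isTRUE(all.equal(tot, object@totalConformers))) {
    return("totalConformers must equal the product of angle counts")
  }
  TRUE
})

#' @describeIn RotorSet-class Number of rotors.
#' @param x A `RotorSet`.
#' @export
rotorCount <- function(x) length(x@rotors)

#' @describeIn RotorSet-class Size of the conformer index space.
#' @export
totalConformers <- function(x) x@totalConformers

setMethod("show", "RotorSet", function(object) {
  cat(sprintf("RotorSet: %d rotor(s), %s conformers\n",
              length(object@rotors),
              format(object@totalConformers, scientific = FALSE)))
  for (k in seq_along(object@rotors)) {
    r <- object@rotors[[k]]
    cat(sprintf("  rotor %d: bond %d-%d, fold %d, %d angle(s)\n",
                k, r$bond[1], r$bond[2], r$fold, length(r$angles)))
  }
})

## ---------------------------------------------------------------------------
## FFContext
## ---------------------------------------------------------------------------

#' MMFF94 evaluation context for one molecule
#'
#' Wraps a handle into the forcefield backend together with the constant part
#' of the MMFF94 energy (bond stretch + angle bend + stretch-bend +
#' out-of-plane), which does not change under torsion driving and is computed
#' once at the input geometry. [variableEnergy()] returns the remaining
#' torsion + van der Waals + electrostatic sum; [totalEnergy()] the full
#' MMFF94 energy.
#'
#' @slot molId integer backend molecule handle.
#' @slot sdf character, the SDF block used to parameterise (kept so the
#'   context can be re-established if the backend restarts).
#' @slot natoms integer atom count.
#' @slot constantTerms numeric, kcal/mol.
#' @slot inputCoords matrix, the input geometry.
#' @exportClass FFContext
setClass("FFContext",
  slots = c(molId = "integer", sdf = "character", natoms = "integer",
            constantTerms = "numeric", inputCoords = "matrix")
)

setMethod("show", "FFContext", function(object) {
  cat(sprintf("FFContext: %d atoms, constant terms %.4f kcal/mol\n",
              object@natoms, object@constantTerms))
})

## ---------------------------------------------------------------------------
## DiversityTree
## ---------------------------------------------------------------------------

#' Hierarchical RMSD diversity tree
#'
#' Levelled tree used to reject near-duplicate conformers with few RMSD
#' evaluations. Level radii descend from 3.0 Angstrom down to the user
#' diversity cutoff `d`; sibling nodes at a level differ by at least that
#' level's radius, and the first child of every parent holds the same
#' conformer as the parent (so its RMSD need not be recomputed on descent).
#' The tree is mutable: an environment holds the nodes, the stored
#' coordinates and an RMSD-evaluation counter.
#'
#' @slot levelRadii numeric, strictly decreasing, last element equals `d`.
#' @slot env environment with fields `root` (list of top-level nodes),
#'   `store` (list of stored heavy-atom coordinate matrices), `meta`
#'   (list of per-conformer metadata), `nrmsd` (evaluation counter).
#' @exportClass DiversityTree
setClass("DiversityTree",
  slots = c(levelRadii = "numeric", env = "environment")
)

setValidity("DiversityTree", function(object) {
  r <- object@levelRadii
  if (length(r) == 0) return("at least one level radius required")
  if (any(diff(r) >= 0)) return("level radii must be strictly decreasing")
  if (any(r <= 0)) return("level radii must be positive")
  TRUE
})

#' @describeIn DiversityTree-class Number of stored conformers.
#' @param tree A `DiversityTree`.
#' @export
treeSize <- function(tree) length(tree@env$store)

#' @describeIn DiversityTree-class RMSD evaluations performed so far.
#' @export
rmsdEvaluations <- function(tree) tree@env$nrmsd

setMethod("show", "DiversityTree", function(object) {
  cat(sprintf("DiversityTree: levels [%s] Angstrom, %d stored, %d RMSD evals\n",
              paste(sprintf("%.3f", object@levelRadii), collapse = ", "),
              length(object@env$store), object@env$nrmsd))
})

## ---------------------------------------------------------------------------
## SearchOptions / RecoveryReport
## ---------------------------------------------------------------------------

#' Options controlling the conformer search
#'
#' @param diversity RMSD diversity cutoff d in Angstrom (required, > 0).
#' @param energyCutoff energy window above the lowest-energy conformer in
#'   kcal/mol (default 50); `Inf` disables the window.
#' @param conformerCap maximum number of conformers tested (default 1e6).
#' @param torlib path to a torsion-library file, or `NULL` for the bundled
#'   default library.
#' @param verbose logical, log per-molecule progress to stderr.
#' @return A `SearchOptions` object.
#' @export
SearchOptions <- function(diversity, energyCutoff = 50, conformerCap = 1e6,
                          torlib = NULL, verbose = FALSE) {
  new("SearchOptions",
      diversity = as.numeric(diversity),
      energyCutoff = as.numeric(energyCutoff),
      conformerCap = as.numeric(conformerCap),
      torlib = if (is.null(torlib)) character() else as.character(torlib),
      verbose = isTRUE(verbose))
}

#' @rdname SearchOptions
#' @exportClass SearchOptions
setClass("SearchOptions",
  slots = c(diversity = "numeric", energyCutoff = "numeric",
            conformerCap = "numeric", torlib = "character", verbose = "logical")
)

setValidity("SearchOptions", function(object) {
  msg <- character()
  if (length(object@diversity) != 1 || !is.finite(object@diversity) ||
      object@diversity <= 0) {
    msg <- c(msg, "diversity must be a single positive number")
  }
  if (object@energyCutoff <= 0) msg <- c(msg, "energyCutoff must be positive (Inf disables)")
  if (object@conformerCap < 1) msg <- c(msg, "conformerCap must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Crystal-recovery benchmark report
#'
#' @slot perMolecule data.frame with one row per molecule: `title`,
#'   `rotatableBonds`, `totalConformers`, `tested`, `lowEnergy`, `diverse`,
#'   `minRmsd` (Angstrom, symmetry-corrected minimum over the ensemble).
#' @slot cutoffs numeric RMSD cutoffs (Angstrom).
#' @slot recovery numeric percent recovery at each cutoff (raw, unrounded).
#' @exportClass RecoveryReport
setClass("RecoveryReport",
  slots = c(perMolecule = "data.frame", cutoffs = "numeric", recovery = "numeric")
)

setValidity("RecoveryReport", function(object) {
  if (length(object@cutoffs) != length(object@recovery)) {
    return("cutoffs and recovery must align")
  }
  if (any(object@recovery < 0 | object@recovery > 100)) {
    return("recovery must lie in [0, 100]")
  }
  TRUE
})

setMethod("show", "RecoveryReport", function(object) {
  cat(sprintf("RecoveryReport: %d molecule(s)\n", nrow(object@perMolecule)))
  for (k in seq_along(object@cutoffs)) {
    cat(sprintf("  recovery at %.1f A: %.1f%%\n",
                object@cutoffs[k], object@recovery[k]))
  }
})
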