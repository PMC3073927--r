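## On-the-fly diversity tree and the robust energy-ordered prune -----------

#' Create an empty diversity tree
#'
#' Level radii descend from 3.0 Angstrom by a factor of 1.5 (3.0, 2.0,
#' 1.333, ...) and stop before the first value at or below the user cutoff
#' `d`, which is appended as the bottom level; a cutoff of 1.6 gives the
#' ladder 3.0, 2.0, 1.6. If `d >= 3.0` the tree has the single level `d`.
#'
#' @param d RMSD diversity cutoff in Angstrom (> 0).
#' @return A [DiversityTree-class].
#' @export
makeDiversityTree <- function(d) {
  if (!is.numeric(d) || length(d) != 1 || !is.finite(d) || d <= 0) {
    stop("diversity cutoff d must be a single positive number")
  }
  radii <- numeric(0)
  r <- 3.0
  while (r > d) {
    radii <- c(radii, r)
    r <- r / 1.5
  }
  radii <- c(radii, d)
  env <- new.env(parent = emptyenv())
  env$root <- list()
  env$store <- list()
  env$meta <- list()
  env$nrmsd <- 0L
  new("DiversityTree", levelRadii = radii, env = env)
}

# A node is list(id = conformer id, children = list of nodes).
.newChain <- function(id, depth) {
  node <- list(id = id, children = list())
  while (depth > 1) {
    node <- list(id = id, children = list(node))
    depth <- depth - 1
  }
  node
}

#' Insert a conformer through the fast (first-match descent) filter
#'
#' Descends the tree from the top: at each level the siblings are scanned in
#' order and the first one within that level's radius is followed (the RMSD
#' to a child holding the same conformer as its parent is reused, not
#' recomputed). If no sibling is within the radius, the conformer is stored
#' as a new sibling with its chain of single children down to the bottom. At
#' the bottom level, any sibling within `d` rejects the conformer. The
#' filter may falsely accept (similar conformers in different branches) but
#' never falsely rejects; the rejection witness is returned.
#'
#' @param tree A [DiversityTree-class] (mutated in place).
#' @param coords heavy-atom coordinate matrix of the new conformer.
#' @param rmsdFun plain heavy-atom RMSD `function(coordsA, coordsB)`.
#' @param meta optional metadata stored with the conformer.
#' @return list `accepted` (logical), `id` (stored id or `NA`), `witness`
#'   (on rejection: list with `id` and `rmsd` of the stored conformer that
#'   proves the new one is within `d`).
#' @export
fastInsert <- function(tree, coords, rmsdFun, meta = NULL) {
  env <- tree@env
  radii <- tree@levelRadii
  L <- length(radii)
  rmsdTo <- function(id) {
    env$nrmsd <- env$nrmsd + 1L
    rmsdFun(coords, env$store[[id]])
  }
  storeConf <- function() {
    id <- length(env$store) + 1L
    env$store[[id]] <- coords
    env$meta[[id]] <- meta
    id
  }

  insertAt <- function(siblings, level, parentRmsd) {
    # parentRmsd: RMSD to the conformer held by the first sibling (same as
    # the parent), already computed one level up; NA at the root.
    for (k in seq_along(siblings)) {
      r <- if (k == 1 && !is.na(parentRmsd)) parentRmsd else rmsdTo(siblings[[k]]$id)
      if (r < radii[level]) {
        if (level == L) {
          return(list(accepted = FALSE, siblings = siblings,
                      witness = list(id = siblings[[k]]$id, rmsd = r)))
        }
        res <- insertAt(siblings[[k]]$children, level + 1, r)
        siblings[[k]]$children <- res$siblings
        return(list(accepted = res$accepted, siblings = siblings,
                    witness = res$witness, id = res$id))
      }
    }
    id <- storeConf()
    siblings[[length(siblings) + 1]] <- .newChain(id, L - level + 1)
    list(accepted = TRUE, siblings = siblings, witness = NULL, id = id)
  }

  res <- insertAt(env$root, 1, NA_real_)
  env$root <- res$siblings
  list(accepted = res$accepted,
       id = if (res$accepted) res$id else NA_integer_,
       witness = res$witness)
}

#' Energy-ordered exact diversity prune
#'
#' The fast filter can retain near-duplicates that landed in different
#' branches. The prune removes them exactly: conformers are sorted by
#' increasing relative energy (ties by conformer index) and kept only if
#' their minimum symmetry-corrected RMSD to every previously kept conformer
#' is at least `d`. This is the exact greedy filter; it is a strictly
#' stronger contract than a second heuristic tree pass, and any tree-based
#' acceleration must reproduce it unchanged.
#'
#' @param ensemble list of [ConformerRecord-class].
#' @param d diversity cutoff in Angstrom.
#' @param rmsdFnSym symmetry-corrected RMSD `function(coordsA, coordsB)`
#'   taking full coordinate matrices and returning Angstrom (see
#'   [symmetryCorrectedRmsd()]).
#' @return the kept conformers, sorted by increasing relative energy.
#' @export
robustPrune <- function(ensemble, d, rmsdFnSym) {
  if (length(ensemble) == 0) return(ensemble)
  e <- vapply(ensemble, relEnergy, numeric(1))
  idx <- vapply(ensemble, confIndex, numeric(1))
  ord <- order(e, idx)
  kept <- list()
  for (k in ord) {
    cand <- ensemble[[k]]
    ok <- TRUE
    for (kc in kept) {
      if (rmsdFnSym(confCoords(kc), confCoords(cand)) < d) { ok <- FALSE; break }
    }
    if (ok) kept[[length(kept) + 1]] <- cand
  }
  kept
}
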