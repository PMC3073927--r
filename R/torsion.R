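## Rotatable bonds, torsion library, fold reduction, torsion driving -------

.defaultGrid <- seq(0, 330, by = 30)

#' Identify the rotatable bonds of a molecule
#'
#' A bond is rotatable when it is an acyclic single bond, both of its atoms
#' are connected to at least two non-hydrogen atoms (the bond partner
#' counts), and neither atom is sp-hybridised. This excludes bonds whose
#' rotation merely interchanges hydrogens (e.g. methyl rotors), which is
#' harmless because RMSD is computed on heavy atoms only.
#'
#' @param mol A [MoleculeGraph-class].
#' @return data.frame with columns `i`, `j` (atom indices), in bond order.
#' @export
findRotatableBonds <- function(mol) {
  b <- mol@bonds
  if (nrow(b) == 0) return(data.frame(i = integer(0), j = integer(0)))
  el <- mol@atoms$element
  hy <- mol@atoms$hybrid
  heavyDeg <- integer(atomCount(mol))
  for (k in seq_len(nrow(b))) {
    if (el[b$j[k]] != "H") heavyDeg[b$i[k]] <- heavyDeg[b$i[k]] + 1L
    if (el[b$i[k]] != "H") heavyDeg[b$j[k]] <- heavyDeg[b$j[k]] + 1L
  }
  ok <- !b$inRing & b$order == 1L & !b$aromatic &
    el[b$i] != "H" & el[b$j] != "H" &
    heavyDeg[b$i] >= 2 & heavyDeg[b$j] >= 2 &
    hy[b$i] != "sp" & hy[b$j] != "sp"
  data.frame(i = b$i[ok], j = b$j[ok])
}

#' Load a torsion library from a `torlib.txt`-style file
#'
#' Plain text: each non-comment line is a 4-atom SMARTS pattern followed by
#' whitespace-separated allowed angles (degrees in \[0, 360)). `#` starts a
#' comment. Rules keep file order; during assignment the first matching rule
#' wins. With `path = NULL` the library bundled with the package is used.
#'
#' @param path file path or `NULL` for the bundled default.
#' @return A [TorsionLibrary-class].
#' @export
loadTorsionLibrary <- function(path = NULL) {
  if (is.null(path) || length(path) == 0 || !nzchar(path[1])) {
    path <- system.file("torlib", "torlib.txt", package = "confabR")
  }
  if (!file.exists(path)) stop("torsion library file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  smarts <- character()
  angles <- list()
  for (ln in seq_along(lines)) {
    raw <- trimws(lines[ln])
    # '#' only starts a comment at the line head: SMARTS use '#' internally
    if (!nzchar(raw) || startsWith(raw, "#")) next
    parts <- strsplit(raw, "\\s+")[[1]]
    if (length(parts) < 2) {
      stop(sprintf("torsion library line %d: need a SMARTS and at least one angle", ln))
    }
    a <- suppressWarnings(as.numeric(parts[-1]))
    if (any(is.na(a))) {
      stop(sprintf("torsion library line %d: non-numeric angle", ln))
    }
    if (any(a < 0 | a >= 360)) {
      stop(sprintf("torsion library line %d: angles must lie in [0, 360)", ln))
    }
    smarts <- c(smarts, parts[1])
    angles <- c(angles, list(sort(unique(a))))
  }
  if (length(smarts) > 0) {
    info <- backendRequest(list(op = "patinfo", patterns = as.list(smarts)))
    for (k in seq_along(smarts)) {
      pk <- info$patterns[[k]]
      if (!isTRUE(pk$valid)) {
        stop("torsion library: invalid SMARTS '", smarts[k], "'")
      }
      if (pk$natoms != 4) {
        stop("torsion library: SMARTS '", smarts[k],
             "' must contain exactly 4 atoms (has ", pk$natoms, ")")
      }
    }
  }
  lib <- new("TorsionLibrary",
             rules = data.frame(smarts = smarts,
                                angles = I(angles),
                                priority = seq_along(smarts)))
  validObject(lib)
  lib
}

# Deterministic reference quadruple for a rotor bond b-c: on each side pick
# the heavy neighbour with the highest (canonical) symmetry class id,
# breaking ties by lowest atom index.
.referenceQuad <- function(mol, b, c, classes) {
  clsOf <- rep(NA_integer_, atomCount(mol))
  clsOf[classes@heavyIdx] <- classes@classId
  pick <- function(centre, exclude) {
    nb <- .atomNeighbours(mol, centre)
    nb <- nb[nb != exclude & mol@atoms$element[nb] != "H"]
    if (length(nb) == 0) return(NA_integer_)
    nb[order(-clsOf[nb], nb)][1]
  }
  a <- pick(b, c)
  d <- pick(c, b)
  c(a, b, c, d)
}

.atomNeighbours <- function(mol, a) {
  b <- mol@bonds
  c(b$j[b$i == a], b$i[b$j == a])
}

# Atoms on the c-side of bond b-c after deleting the bond.
.sideOf <- function(mol, b, c) {
  n <- atomCount(mol)
  seen <- logical(n)
  seen[b] <- TRUE
  stack <- c
  seen[c] <- TRUE
  out <- integer(0)
  while (length(stack) > 0) {
    cur <- stack[length(stack)]
    stack <- stack[-length(stack)]
    out <- c(out, cur)
    for (nb in .atomNeighbours(mol, cur)) {
      if (!seen[nb]) { seen[nb] <- TRUE; stack <- c(stack, nb) }
    }
  }
  sort(out)
}

#' Assign allowed torsion angles to rotatable bonds from a library
#'
#' For each bond, substructure matches of every library SMARTS are computed
#' and the first rule (file order) whose pattern's 2nd-3rd atoms map onto the
#' bond wins; bonds with no match get the default 12-angle 30-degree grid.
#' Rotors are returned pre-fold-reduction (fold 1), ordered by centrality
#' (bond eccentricity on the heavy-atom graph, most central first, ties by
#' discovery order).
#'
#' @param mol A [MoleculeGraph-class].
#' @param bonds data.frame from [findRotatableBonds()].
#' @param library A [TorsionLibrary-class] (default: bundled library).
#' @param sdfText the molecule's SDF block (needed for SMARTS matching);
#'   omit to regenerate from `conf`.
#' @param conf optional [ConformerRecord-class] used to regenerate SDF text.
#' @return A [RotorSet-class] with fold 1 on every rotor.
#' @export
assignTorsionValues <- function(mol, bonds, library = loadTorsionLibrary(),
                                sdfText = NULL, conf = NULL) {
  if (nrow(bonds) == 0) {
    return(new("RotorSet", rotors = list(), totalConformers = 1))
  }
  if (is.null(sdfText)) {
    if (is.null(conf)) stop("need sdfText or conf for SMARTS matching")
    sdfText <- .sdfBlock(mol, confCoords(conf), molTitle(mol))
  }
  classes <- computeSymmetryClasses(mol)
  rules <- library@rules
  matchesByRule <- list()
  if (nrow(rules) > 0) {
    ld <- backendRequest(list(op = "load", sdf = sdfText))
    ans <- backendRequest(list(op = "smarts", id = ld$id,
                               patterns = as.list(rules$smarts)))
    backendRequest(list(op = "release", id = ld$id))
    matchesByRule <- lapply(ans$patterns, function(p) {
      if (length(p$matches) == 0) return(matrix(integer(0), ncol = 0))
      do.call(rbind, lapply(p$matches, function(m) as.integer(m) + 1L))
    })
  }
  rotors <- vector("list", nrow(bonds))
  for (k in seq_len(nrow(bonds))) {
    bb <- bonds$i[k]; cc <- bonds$j[k]
    ang <- NULL
    for (r in seq_along(matchesByRule)) {
      mm <- matchesByRule[[r]]
      if (length(mm) == 0) next
      hit <- (mm[, 2] == bb & mm[, 3] == cc) | (mm[, 2] == cc & mm[, 3] == bb)
      if (any(hit)) { ang <- rules$angles[[r]]; break }
    }
    if (is.null(ang)) ang <- .defaultGrid
    quad <- .referenceQuad(mol, bb, cc, classes)
    side_c <- .sideOf(mol, bb, cc)
    side_b <- .sideOf(mol, cc, bb)
    # smaller side moves; ties broken toward the side not containing atom 1
    if (length(side_c) < length(side_b) ||
        (length(side_c) == length(side_b) && !(1L %in% side_c))) {
      moving <- setdiff(side_c, cc)
    } else {
      moving <- setdiff(side_b, bb)
      quad <- rev(quad)          # drive the dihedral from the other side
      tmp <- bb; bb <- cc; cc <- tmp
    }
    rotors[[k]] <- list(bond = c(bb, cc), quad = quad, angles = ang,
                        fold = 1L, moving = moving)
  }
  .orderRotorsByCentrality(mol, rotors)
}

# Most central rotor first: centrality = max over heavy atoms of the smaller
# topological distance to the two bond atoms (heavy-atom graph).
.orderRotorsByCentrality <- function(mol, rotors) {
  if (length(rotors) == 0) {
    return(new("RotorSet", rotors = list(), totalConformers = 1))
  }
  hg <- .heavyGraph(mol)
  g <- igraph::make_empty_graph(n = hg$n, directed = FALSE)
  if (nrow(hg$edges) > 0) g <- igraph::add_edges(g, t(hg$edges))
  D <- igraph::distances(g)
  pos <- match(seq_len(atomCount(mol)), mol@heavyIdx)
  ecc <- vapply(rotors, function(r) {
    pb <- pos[r$bond[1]]; pc <- pos[r$bond[2]]
    max(pmin(D[pb, ], D[pc, ]))
  }, numeric(1))
  ord <- order(ecc, seq_along(rotors))
  rotors <- rotors[ord]
  new("RotorSet", rotors = rotors,
      totalConformers = prod(vapply(rotors, function(r) length(r$angles), numeric(1))))
}

#' Reduce allowed torsion angles by topological symmetry folds
#'
#' At each end of a rotor: a 2-fold symmetry is declared when the end atom is
#' an sp2 carbon whose two neighbouring heavy atoms affected by the rotation
#' share a symmetry class; a 3-fold symmetry when it is an sp3 carbon with
#' three same-class heavy neighbours. Folds at both ends multiply, and the
#' allowed angles are restricted to those below 360/fold: a combined 2-fold
#' and 3-fold symmetry leaves only angles below 60 degrees.
#'
#' @param mol A [MoleculeGraph-class].
#' @param rotorset A [RotorSet-class] (pre-reduction).
#' @param classes A [SymmetryClasses-class] for `mol`.
#' @return A [RotorSet-class] with folds applied.
#' @export
applyFoldReduction <- function(mol, rotorset, classes = computeSymmetryClasses(mol)) {
  clsOf <- rep(NA_integer_, atomCount(mol))
  clsOf[classes@heavyIdx] <- classes@classId
  el <- mol@atoms$element
  hy <- mol@atoms$hybrid
  foldAt <- function(centre, partner) {
    if (el[centre] != "C") return(1L)          # the rule names carbon only
    nb <- .atomNeighbours(mol, centre)
    nb <- nb[nb != partner & el[nb] != "H"]
    if (hy[centre] == "sp2" && length(nb) == 2 &&
        clsOf[nb[1]] == clsOf[nb[2]]) return(2L)
    if (hy[centre] == "sp3" && length(nb) == 3 &&
        length(unique(clsOf[nb])) == 1) return(3L)
    1L
  }
  rotors <- lapply(rotorset@rotors, function(r) {
    f <- foldAt(r$bond[1], r$bond[2]) * foldAt(r$bond[2], r$bond[1])
    if (f > 1) {
      keep <- r$angles < 360 / f
      if (any(keep)) {
        r$angles <- r$angles[keep]
      }                                        # never empty the angle set
      r$fold <- as.integer(f)
    }
    r
  })
  new("RotorSet", rotors = rotors,
      totalConformers = prod(vapply(rotors, function(r) length(r$angles), numeric(1))))
}

#' Measure a dihedral angle (degrees in \[0, 360))
#'
#' @param coords coordinate matrix.
#' @param quad integer vector (a, b, c, d) of atom indices.
#' @return dihedral in degrees.
#' @export
measureTorsion <- function(coords, quad) {
  p <- coords[quad, , drop = FALSE]
  b1 <- p[2, ] - p[1, ]; b2 <- p[3, ] - p[2, ]; b3 <- p[4, ] - p[3, ]
  n1 <- .cross3(b1, b2); n2 <- .cross3(b2, b3)
  m1 <- .cross3(n1, b2 / sqrt(sum(b2^2)))
  x <- sum(n1 * n2); y <- sum(m1 * n2)
  ang <- atan2(y, x) * 180 / pi
  (ang %% 360)
}

.cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3], u[1] * v[2] - u[2] * v[1])
}

#' Set a rotor's dihedral by rigid rotation of its moving fragment
#'
#' The moving fragment is rotated about the b-c axis so the rotor's reference
#' quadruple reads `angleDeg` (within 1e-6 degrees). All bond lengths and
#' angles, and every dihedral not involving the rotor bond, are unchanged.
#'
#' @param mol A [MoleculeGraph-class].
#' @param conf A [ConformerRecord-class].
#' @param rotor one rotor from a [RotorSet-class].
#' @param angleDeg target dihedral in \[0, 360).
#' @return A new [ConformerRecord-class].
#' @export
setTorsion <- function(mol, conf, rotor, angleDeg) {
  stopifnot(angleDeg >= 0, angleDeg < 360)
  coords <- confCoords(conf)
  quad <- rotor$quad
  b <- coords[quad[2], ]; cc <- coords[quad[3], ]
  axis <- cc - b
  nrm <- sqrt(sum(axis^2))
  if (nrm < 1e-8) stop("degenerate torsion frame")
  v1 <- coords[quad[1], ] - b
  v4 <- coords[quad[4], ] - cc
  if (sqrt(sum(.cross3(v1, axis)^2)) / (nrm * sqrt(sum(v1^2))) < 1e-7 ||
      sqrt(sum(.cross3(v4, axis)^2)) / (nrm * sqrt(sum(v4^2))) < 1e-7) {
    stop("degenerate torsion frame")
  }
  current <- measureTorsion(coords, quad)
  delta <- (angleDeg - current) %% 360
  if (delta > 1e-12 && 360 - delta > 1e-12) {
    u <- axis / nrm
    # rotating the c-side fragment by +theta about b->c decreases the
    # measured a-b-c-d dihedral, hence the sign flip
    th <- -delta * pi / 180
    K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
                nrow = 3, byrow = TRUE)
    R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
    mv <- rotor$moving
    coords[mv, ] <- sweep(sweep(coords[mv, , drop = FALSE], 2, b) %*% t(R), 2, b, `+`)
  }
  ConformerRecord(coords, relEnergy(conf), confIndex(conf))
}

# Full rotor pipeline: find bonds, assign angles, fold-reduce.
rotorPipeline <- function(mol, conf, torlib = NULL) {
  lib <- if (is(torlib, "TorsionLibrary")) torlib else loadTorsionLibrary(torlib)
  bonds <- findRotatableBonds(mol)
  rs <- assignTorsionValues(mol, bonds, lib, conf = conf)
  applyFoldReduction(mol, rs)
}
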