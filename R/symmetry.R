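## Topological symmetry: Morgan-style classes and graph automorphisms ------

# Heavy-atom adjacency with bond orders (aromatic counted 1.5 so Kekule
# structures of the same ring give identical invariants).
.heavyGraph <- function(mol) {
  heavy <- mol@heavyIdx
  pos <- match(seq_len(atomCount(mol)), heavy)   # atom index -> heavy position
  b <- mol@bonds
  keep <- !is.na(pos[b$i]) & !is.na(pos[b$j])
  hb <- b[keep, , drop = FALSE]
  ord <- ifelse(hb$aromatic, 1.5, hb$order)
  list(
    n = length(heavy),
    edges = cbind(pos[hb$i], pos[hb$j]),
    order = ord,
    element = mol@atoms$element[heavy],
    charge = mol@atoms$charge[heavy],
    inRing = mol@atoms$inRing[heavy]
  )
}

.neighbourList <- function(n, edges, order) {
  nb <- vector("list", n)
  bo <- vector("list", n)
  for (k in seq_len(nrow(edges))) {
    i <- edges[k, 1]; j <- edges[k, 2]
    nb[[i]] <- c(nb[[i]], j); bo[[i]] <- c(bo[[i]], order[k])
    nb[[j]] <- c(nb[[j]], i); bo[[j]] <- c(bo[[j]], order[k])
  }
  list(nb = nb, bo = bo)
}

#' Topological symmetry classes of the heavy atoms
#'
#' Iterative refinement to a fixed point, seeded with (element, heavy-atom
#' degree, formal charge, ring membership, sum of bond orders) and refined by
#' the sorted multiset of (bond order, neighbour class) pairs. Class ids are
#' canonical: they are ranks of sorted signature strings, so relabelling the
#' atoms of an isomorphic graph yields the identical class multiset.
#'
#' @param mol A [MoleculeGraph-class] with at least one heavy atom.
#' @return A [SymmetryClasses-class].
#' @export
computeSymmetryClasses <- function(mol) {
  hg <- .heavyGraph(mol)
  if (hg$n < 1) stop("molecule has no heavy atoms")
  nl <- .neighbourList(hg$n, hg$edges, hg$order)
  degree <- vapply(nl$nb, length, integer(1))
  ordsum <- vapply(nl$bo, function(x) sum(x), numeric(1))
  sig <- sprintf("%s|%d|%d|%d|%.1f", hg$element, degree, hg$charge,
                 as.integer(hg$inRing), ordsum)
  cls <- match(sig, sort(unique(sig)))
  # refine until the partition stops splitting (each step can only split)
  repeat {
    sig2 <- vapply(seq_len(hg$n), function(a) {
      if (degree[a] == 0) return(sprintf("%d|", cls[a]))
      pairs <- sprintf("%.1f:%d", nl$bo[[a]], cls[nl$nb[[a]]])
      sprintf("%d|%s", cls[a], paste(sort(pairs), collapse = ","))
    }, character(1))
    cls2 <- match(sig2, sort(unique(sig2)))
    if (length(unique(cls2)) == length(unique(cls))) {
      cls <- cls2
      break
    }
    cls <- cls2
  }
  new("SymmetryClasses", classId = as.integer(cls), heavyIdx = mol@heavyIdx)
}

# Compose permutations: (p %p% q)[i] = p[q[i]]
.permCompose <- function(p, q) p[q]

#' Enumerate graph automorphisms of the heavy-atom graph
#'
#' Automorphisms preserve element, formal charge and bond order (aromatic
#' bonds normalised). Bond orders are encoded as coloured edge-subdivision
#' vertices so that igraph's BLISS search applies; the returned generators
#' are closed under composition up to `cap` elements.
#'
#' @param mol A [MoleculeGraph-class].
#' @param cap maximum number of automorphisms to enumerate (default 5000).
#'   If the group is larger, the set is truncated and `truncated` is set;
#'   downstream symmetry-corrected RMSD then degrades gracefully (it is
#'   still an upper bound, minimised over the subset that was kept).
#' @return An [AutomorphismSet-class].
#' @export
enumerateAutomorphisms <- function(mol, cap = 5000L) {
  stopifnot(cap >= 1)
  hg <- .heavyGraph(mol)
  n <- hg$n
  identity <- seq_len(n)
  if (n <= 1 || nrow(hg$edges) == 0) {
    return(new("AutomorphismSet", perms = list(identity),
               heavyIdx = mol@heavyIdx, truncated = FALSE))
  }
  # vertex colours from invariants that any automorphism must preserve
  vsig <- sprintf("%s|%d|%d", hg$element, hg$charge, as.integer(hg$inRing))
  vcol <- match(vsig, sort(unique(vsig)))
  # subdivide each edge with a vertex coloured by bond order
  ne <- nrow(hg$edges)
  ecol <- max(vcol) + match(hg$order, sort(unique(hg$order)))
  edges <- integer(0)
  for (k in seq_len(ne)) {
    mid <- n + k
    edges <- c(edges, hg$edges[k, 1], mid, mid, hg$edges[k, 2])
  }
  g <- igraph::make_empty_graph(n = n + ne, directed = FALSE)
  g <- igraph::add_edges(g, edges)
  colors <- c(vcol, ecol)
  gens <- igraph::automorphism_group(g, colors = colors)
  gens <- lapply(gens, function(p) as.integer(p[seq_len(n)]))
  # close under composition (BFS over the group) up to cap
  seen <- new.env(parent = emptyenv())
  keyOf <- function(p) paste(p, collapse = ",")
  assign(keyOf(identity), TRUE, envir = seen)
  out <- list(identity)
  queue <- list(identity)
  truncated <- FALSE
  while (length(queue) > 0 && !truncated) {
    cur <- queue[[1]]; queue <- queue[-1]
    for (gp in gens) {
      nxt <- .permCompose(cur, gp)
      k <- keyOf(nxt)
      if (!exists(k, envir = seen, inherits = FALSE)) {
        if (length(out) >= cap) { truncated <- TRUE; break }
        assign(k, TRUE, envir = seen)
        out[[length(out) + 1]] <- nxt
        queue[[length(queue) + 1]] <- nxt
      }
    }
  }
  if (truncated) {
    warning("automorphism enumeration capped at ", cap,
            "; symmetry-corrected RMSD will minimise over a subset")
  }
  new("AutomorphismSet", perms = out, heavyIdx = mol@heavyIdx,
      truncated = truncated)
}
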