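## Perception of ring membership, aromaticity and hybridisation ------------

# Ring bonds are the non-bridge edges of the molecular graph; ring atoms are
# the atoms incident to a ring bond.
perceiveRings <- function(natoms, bonds) {
  if (nrow(bonds) == 0) {
    return(list(atomInRing = logical(natoms), bondInRing = logical(0)))
  }
  g <- igraph::graph_from_edgelist(cbind(bonds$i, bonds$j), directed = FALSE)
  if (igraph::vcount(g) < natoms) {
    g <- igraph::add_vertices(g, natoms - igraph::vcount(g))
  }
  br <- igraph::bridges(g)
  bondInRing <- rep(TRUE, nrow(bonds))
  bondInRing[as.integer(br)] <- FALSE
  atomInRing <- logical(natoms)
  ring_b <- bonds[bondInRing, , drop = FALSE]
  atomInRing[unique(c(ring_b$i, ring_b$j))] <- TRUE
  list(atomInRing = atomInRing, bondInRing = bondInRing)
}

# Hybridisation from bond orders: sp for linear centres with a triple bond or
# cumulated double bonds; sp2 for atoms carrying one double bond or aromatic
# flags; sp3 for saturated centres (this includes hypervalent sulfur as in
# sulfones, whose two S=O bonds do not make it linear).
perceiveHybridisation <- function(elements, bonds, aromaticAtom) {
  n <- length(elements)
  ndouble <- integer(n); ntriple <- integer(n); degree <- integer(n)
  if (nrow(bonds) > 0) {
    for (k in seq_len(nrow(bonds))) {
      i <- bonds$i[k]; j <- bonds$j[k]
      degree[i] <- degree[i] + 1L; degree[j] <- degree[j] + 1L
      if (!bonds$aromatic[k]) {
        if (bonds$order[k] == 2L) { ndouble[i] <- ndouble[i] + 1L; ndouble[j] <- ndouble[j] + 1L }
        if (bonds$order[k] == 3L) { ntriple[i] <- ntriple[i] + 1L; ntriple[j] <- ntriple[j] + 1L }
      }
    }
  }
  hy <- character(n)
  for (a in seq_len(n)) {
    if (elements[a] == "H") { hy[a] <- "other"; next }
    if (degree[a] <= 2 && (ntriple[a] >= 1 || ndouble[a] >= 2)) { hy[a] <- "sp"; next }
    if (aromaticAtom[a] || (ndouble[a] >= 1 && degree[a] <= 3)) { hy[a] <- "sp2"; next }
    if (degree[a] >= 1) { hy[a] <- "sp3"; next }
    hy[a] <- "other"
  }
  hy
}

# Aromaticity is delegated to the backend's perception on the raw record; a
# Kekule input therefore normalises to the same aromatic flags as an input
# with explicit aromatic bonds, which keeps symmetry classes and
# automorphisms independent of the Kekule structure chosen by the writer.
perceiveAromaticity <- function(sdfText) {
  ans <- backendRequest(list(op = "perceive", sdf = sdfText))
  list(
    atoms = as.integer(unlist(ans$aromatic_atoms)) + 1L,
    bonds = if (length(ans$aromatic_bonds) == 0) {
      matrix(integer(0), ncol = 2)
    } else {
      do.call(rbind, lapply(ans$aromatic_bonds, function(p) as.integer(p) + 1L))
    }
  )
}
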