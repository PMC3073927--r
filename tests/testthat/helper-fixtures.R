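# Shared fixtures and small constructors. Everything is built in code or
# loaded from the package's embedded SDF blocks; nothing touches the network.

# cache: loading a fixture costs a backend round-trip, reuse across tests
.fx_cache <- new.env(parent = emptyenv())
fx <- function(name) {
  if (is.null(.fx_cache[[name]])) .fx_cache[[name]] <- loadFixture(name)
  .fx_cache[[name]]
}

.ctx_cache <- new.env(parent = emptyenv())
fxCtx <- function(name) {
  if (is.null(.ctx_cache[[name]])) {
    f <- fx(name)
    .ctx_cache[[name]] <- setupForcefield(f$mol, f$conf)
  }
  .ctx_cache[[name]]
}

fxRotors <- function(name, torlib = NULL) {
  f <- fx(name)
  confabR:::rotorPipeline(f$mol, f$conf, torlib)
}

# rotation matrix about a unit axis
rotAbout <- function(axis, theta) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, byrow = TRUE)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

applyRigid <- function(coords, R, t = c(0, 0, 0)) {
  sweep(coords %*% t(R), 2, t, `+`)
}

# flip a para-substituted ring 180 degrees about the axis through two atoms
ringFlip <- function(coords, axisAtoms, ringAtoms) {
  b <- coords[axisAtoms[1], ]
  ax <- coords[axisAtoms[2], ] - b
  R <- rotAbout(ax, pi)
  out <- coords
  out[ringAtoms, ] <- sweep(sweep(coords[ringAtoms, , drop = FALSE], 2, b) %*% t(R),
                            2, b, `+`)
  out
}

# benzene: exact hexagon, for the automorphism count check (dihedral group)
benzeneGraph <- function() {
  atoms <- data.frame(
    element = c(rep("C", 6), rep("H", 6)),
    charge = 0L,
    inRing = c(rep(TRUE, 6), rep(FALSE, 6)),
    hybrid = c(rep("sp2", 6), rep("other", 6))
  )
  bonds <- data.frame(
    i = c(1:6, 1:6),
    j = c(2:6, 1, 7:12),
    order = c(rep(1L, 6), rep(1L, 6)),
    aromatic = c(rep(TRUE, 6), rep(FALSE, 6)),
    inRing = c(rep(TRUE, 6), rep(FALSE, 6))
  )
  new("MoleculeGraph", atoms = atoms, bonds = bonds, title = "benzene",
      heavyIdx = 1:6)
}

# apply an atom permutation to a MoleculeGraph (new index of old atom k is
# perm[k]); used for relabelling-invariance properties
permuteMolecule <- function(mol, perm) {
  inv <- order(perm)
  atoms <- mol@atoms[inv, , drop = FALSE]
  rownames(atoms) <- NULL
  bonds <- mol@bonds
  bonds$i <- perm[bonds$i]
  bonds$j <- perm[bonds$j]
  new("MoleculeGraph", atoms = atoms, bonds = bonds, title = mol@title,
      heavyIdx = which(atoms$element != "H"))
}

# random torsion-driven ensembles with planted near-duplicates; energies are
# synthetic (the prune only consumes the ordering)
randomEnsemble <- function(name, n, seed, jitter = 2) {
  set.seed(seed)
  f <- fx(name)
  rs <- fxRotors(name)
  nr <- rotorCount(rs)
  base <- max(2L, ceiling(n / 3))
  assigns <- replicate(base, vapply(rs@rotors, function(r) sample(r$angles, 1),
                                    numeric(1)), simplify = FALSE)
  out <- vector("list", n)
  for (k in seq_len(n)) {
    a <- assigns[[((k - 1) %% base) + 1]]
    a <- (a + stats::rnorm(nr, 0, jitter)) %% 360
    conf <- f$conf
    for (r in seq_len(nr)) conf <- setTorsion(f$mol, conf, rs@rotors[[r]], a[r])
    out[[k]] <- ConformerRecord(confCoords(conf), stats::runif(1, 0, 20), k - 1)
  }
  out
}

# a point in R^3 disguised as a one-atom conformer; with the Euclidean
# "RMSD" below this gives exact control over distances in tree tests
pt <- function(...) matrix(c(...), 1, 3)
ptDist <- function(a, b) sqrt(sum((a - b)^2))
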