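# Independent brute-force oracles. These deliberately avoid the package's
# own algorithms: permutation search instead of refinement + BLISS, numeric
# rotation optimisation instead of Kabsch, quadratic greedy filters instead
# of trees. Expected values in tests come from these.

# all heavy-atom graph automorphisms by exhaustive permutation search
bruteAutomorphisms <- function(mol) {
  hg <- confabR:::.heavyGraph(mol)
  n <- hg$n
  adj <- matrix(0, n, n)
  if (nrow(hg$edges) > 0) {
    for (k in seq_len(nrow(hg$edges))) {
      i <- hg$edges[k, 1]; j <- hg$edges[k, 2]
      adj[i, j] <- adj[j, i] <- hg$order[k]
    }
  }
  lab <- paste(hg$element, hg$charge)
  perms <- list()
  gen <- function(partial, remaining) {
    if (length(remaining) == 0) {
      perms[[length(perms) + 1]] <<- partial
      return(invisible())
    }
    k <- length(partial) + 1
    for (cand in remaining) {
      if (lab[cand] != lab[k]) next
      ok <- TRUE
      for (prev in seq_len(k - 1)) {
        if (adj[k, prev] != adj[cand, partial[prev]]) { ok <- FALSE; break }
      }
      if (ok) gen(c(partial, cand), setdiff(remaining, cand))
    }
  }
  gen(integer(0), seq_len(n))
  perms
}

# orbits (symmetry classes) induced by the brute-force automorphism group
bruteOrbits <- function(mol) {
  perms <- bruteAutomorphisms(mol)
  n <- length(perms[[1]])
  orbit <- seq_len(n)
  for (p in perms) {
    for (k in seq_len(n)) {
      a <- min(orbit[k], orbit[p[k]])
      orbit[orbit == orbit[k] | orbit == orbit[p[k]]] <- a
    }
  }
  match(orbit, sort(unique(orbit)))
}

# minimum RMSD over proper rotations by numeric optimisation (Euler angles,
# multi-start) -- independent of the SVD route
rmsdOptimOracle <- function(A, B, nstart = 24) {
  Ac <- sweep(A, 2, colMeans(A))
  Bc <- sweep(B, 2, colMeans(B))
  obj <- function(ang) {
    cz <- cos(ang[1]); sz <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cx <- cos(ang[3]); sx <- sin(ang[3])
    Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
    Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
    Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
    R <- Rz %*% Ry %*% Rx
    sqrt(mean(rowSums((Ac - Bc %*% t(R))^2)))
  }
  best <- Inf
  set.seed(421)
  for (s in seq_len(nstart)) {
    start <- stats::runif(3, 0, 2 * pi)
    res <- stats::optim(start, obj, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-14))
    res <- stats::optim(res$par, obj, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-14))
    if (res$value < best) best <- res$value
  }
  best
}

# exact energy-ordered greedy diversity filter, O(n^2), no tree
oracleGreedyPrune <- function(ensemble, d, rmsdFn) {
  e <- vapply(ensemble, relEnergy, numeric(1))
  idx <- vapply(ensemble, confIndex, numeric(1))
  kept <- list()
  for (k in order(e, idx)) {
    cand <- ensemble[[k]]
    ok <- TRUE
    for (kc in kept) {
      if (rmsdFn(confCoords(kc), confCoords(cand)) < d) { ok <- FALSE; break }
    }
    if (ok) kept[[length(kept) + 1]] <- cand
  }
  kept
}

# brute-force reference pipeline: every grid point in ascending index order,
# energy window against the global grid minimum, exact greedy filter
oracleGenerate <- function(mol, conf0, d, ecut = 50, torlib = NULL) {
  rs <- confabR:::rotorPipeline(mol, conf0, torlib)
  ctx <- setupForcefield(mol, conf0)
  N <- totalConformers(rs)
  confs <- lapply(seq_len(N) - 1, function(ix) {
    ang <- confabR:::decodeIndex(rs, ix)
    confabR:::buildConformer(mol, conf0, rs, ang, ix)
  })
  ev <- variableEnergy(ctx, confs)
  rel <- ev - min(ev)
  keep <- which(rel <= ecut)
  recs <- lapply(keep, function(k) ConformerRecord(confCoords(confs[[k]]), rel[k], k - 1))
  autos <- enumerateAutomorphisms(mol)
  symFn <- function(a, b) symmetryCorrectedRmsd(mol, a, b, autos)$rmsd
  oracleGreedyPrune(recs, d, symFn)
}

# MMFF94 term totals from Open Babel's obenergy (independent implementation)
obenergyTerms <- function(sdfPath) {
  ob <- Sys.which("obenergy")
  if (!nzchar(ob)) return(NULL)
  out <- suppressWarnings(system2(ob, c("-ff", "MMFF94", shQuote(sdfPath)),
                                  stdout = TRUE, stderr = FALSE))
  g <- function(pat) {
    ln <- grep(pat, out, value = TRUE)
    if (length(ln) == 0) return(NA_real_)
    as.numeric(sub(".*=\\s*(-?[0-9.]+).*", "\\1", ln[1]))
  }
  list(
    bond = g("TOTAL BOND STRETCHING"), angle = g("TOTAL ANGLE BENDING"),
    strbnd = g("TOTAL STRETCH BENDING"), oop = g("TOTAL OUT-OF-PLANE"),
    torsion = g("TOTAL TORSIONAL"), vdw = g("TOTAL VAN DER WAALS"),
    ele = g("TOTAL ELECTROSTATIC"), total = g("^TOTAL ENERGY")
  )
}
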