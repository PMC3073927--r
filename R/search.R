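## Conformer index space, LFSR traversal, greedy seed, generation loop -----

#' Pseudorandom enumeration of 1..n by linear feedback shift register
#'
#' Chooses the smallest register width k with `2^k - 1 >= n`, runs the
#' maximal-length LFSR (published tap table, deterministic start state) and
#' skips emitted values above `n`, so exactly the set `{1..n}` is produced,
#' each value once, in pseudorandom order with no memory overhead. Callers
#' map `v -> v - 1` for 0-based conformer indices.
#'
#' @param n upper end of the range (>= 1; at most 2^32 - 1).
#' @param take emit only the first `take` values (default all `n`).
#' @return numeric vector of distinct integers in 1..n.
#' @export
lfsrSequence <- function(n, take = n) {
  lfsr_take_cpp(as.numeric(n), as.numeric(take))
}

# index (0-based, double) -> one allowed angle per rotor; rotor 1 least
# significant digit of the mixed radix number.
decodeIndex <- function(rotorset, index) {
  vapply(rotorset@rotors, function(r) {
    nk <- length(r$angles)
    digit <- index %% nk
    index <<- (index - digit) / nk
    r$angles[digit + 1]
  }, numeric(1))
}

encodeIndex <- function(rotorset, angles) {
  idx <- 0
  mult <- 1
  for (k in seq_along(rotorset@rotors)) {
    r <- rotorset@rotors[[k]]
    pos <- match(TRUE, abs(r$angles - angles[k]) < 1e-6) - 1
    if (is.na(pos)) stop("angle not in the rotor's allowed set")
    idx <- idx + pos * mult
    mult <- mult * length(r$angles)
  }
  idx
}

# Apply a full torsion assignment to the input conformer.
buildConformer <- function(mol, conf0, rotorset, angles, index = 0) {
  conf <- conf0
  for (k in seq_along(rotorset@rotors)) {
    conf <- setTorsion(mol, conf, rotorset@rotors[[k]], angles[k])
  }
  ConformerRecord(confCoords(conf), 0, index)
}

#' Greedy low-energy seed conformer
#'
#' Optimises each torsion in turn, most central first and proceeding
#' outwards, setting it to the allowed angle with the lowest variable
#' energy while the others stay fixed. Because a single greedy pass is
#' order-dependent, it is repeated for up to 16 orderings obtained by
#' permuting the (at most) four most central torsions (lexicographic order,
#' remaining rotors kept in centrality order); each pass starts from the
#' input geometry. The lowest total energy found becomes the reference for
#' the energy window.
#'
#' @param mol A [MoleculeGraph-class].
#' @param rotorset A non-empty [RotorSet-class].
#' @param ctx An [FFContext-class] (its stored input geometry seeds the
#'   passes).
#' @return list with `conf` (the seed [ConformerRecord-class]), `totalRef`
#'   and `variableRef` (kcal/mol reference energies).
#' @export
greedySeed <- function(mol, rotorset, ctx) {
  nr <- rotorCount(rotorset)
  stopifnot(nr >= 1)
  conf0 <- ConformerRecord(ctx@inputCoords)
  ncentral <- min(4L, nr)
  perms <- .lexPermutations(seq_len(ncentral))
  if (length(perms) > 16) perms <- perms[1:16]
  rest <- if (nr > ncentral) (ncentral + 1L):nr else integer(0)

  bestVar <- Inf
  bestConf <- NULL
  for (p in perms) {
    ordering <- c(p, rest)
    conf <- conf0
    for (rk in ordering) {
      rotor <- rotorset@rotors[[rk]]
      cand <- lapply(rotor$angles, function(a) setTorsion(mol, conf, rotor, a))
      ev <- variableEnergy(ctx, cand)
      pick <- which.min(ev)   # ties: lowest angle (angles sorted ascending)
      conf <- cand[[pick]]
    }
    ev <- variableEnergy(ctx, conf)
    if (ev < bestVar) {
      bestVar <- ev
      bestConf <- conf
    }
  }
  angles <- vapply(seq_len(nr), function(k) {
    measureTorsion(confCoords(bestConf), rotorset@rotors[[k]]$quad)
  }, numeric(1))
  list(conf = ConformerRecord(confCoords(bestConf)),
       variableRef = bestVar,
       totalRef = bestVar + ctx@constantTerms,
       seedAngles = angles)
}

.lexPermutations <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (k in seq_along(x)) {
    for (rest in .lexPermutations(x[-k])) out[[length(out) + 1]] <- c(x[k], rest)
  }
  out
}

#' Generate the diverse low-energy conformer ensemble of a molecule
#'
#' The main driver: identifies rotors and allowed angles (with symmetry-fold
#' reduction), finds a greedy low-energy reference, then iterates the
#' conformer index space in LFSR order up to `conformerCap`. Each conformer
#' is built by torsion driving, its energy taken relative to the lowest
#' energy seen so far (the reference updates downwards mid-search if a lower
#' energy appears); conformers above the energy window are discarded, the
#' rest pass through the fast diversity tree. Afterwards the stored set is
#' re-filtered against the final reference and pruned exactly with the
#' symmetry-corrected RMSD.
#'
#' @param mol A [MoleculeGraph-class].
#' @param conf0 input [ConformerRecord-class] (reasonable 3D geometry).
#' @param options A [SearchOptions-class] (see [SearchOptions()]).
#' @return list with `ensemble` (list of [ConformerRecord-class], sorted by
#'   relative energy), `stats` (tested / low-energy / stored / diverse
#'   counts, rotor count, total conformers, RMSD evaluation count).
#' @export
generateConformers <- function(mol, conf0, options) {
  validObject(options)
  d <- options@diversity
  rotorset <- rotorPipeline(mol, conf0, if (length(options@torlib)) options@torlib else NULL)
  nr <- rotorCount(rotorset)
  log_ <- function(...) if (options@verbose) message(sprintf(...))

  if (nr == 0) {
    log_("mol=%s rotors=0 conformers=1", molTitle(mol))
    return(list(
      ensemble = list(ConformerRecord(confCoords(conf0), 0, 0)),
      stats = list(rotors = 0L, totalConformers = 1, tested = 1L,
                   lowEnergy = 1L, stored = 1L, diverse = 1L, rmsdEvals = 0L)
    ))
  }

  ctx <- setupForcefield(mol, conf0)
  seed <- greedySeed(mol, rotorset, ctx)
  erefVar <- seed$variableRef

  N <- totalConformers(rotorset)
  m <- min(N, options@conformerCap)
  indices <- lfsrSequence(N, m) - 1

  # geometries + variable energies for all tested indices (batched)
  confs <- lapply(indices, function(ix) {
    buildConformer(mol, conf0, rotorset, decodeIndex(rotorset, ix), ix)
  })
  evar <- variableEnergy(ctx, confs)

  tree <- makeDiversityTree(d)
  heavy <- mol@heavyIdx
  rmsdFun <- function(a, b) kabsch_rmsd_cpp(a, b)
  storedIdx <- integer(0)
  nlow <- 0L
  for (k in seq_along(indices)) {
    if (evar[k] < erefVar) erefVar <- evar[k]   # lower reference from now on
    rel <- evar[k] - erefVar
    if (rel > options@energyCutoff) next
    nlow <- nlow + 1L
    res <- fastInsert(tree, confCoords(confs[[k]])[heavy, , drop = FALSE],
                      rmsdFun, meta = k)
    if (res$accepted) storedIdx <- c(storedIdx, k)
  }

  # re-filter stored conformers against the final reference, then prune
  stored <- lapply(storedIdx, function(k) {
    ConformerRecord(confCoords(confs[[k]]), evar[k] - erefVar, indices[k])
  })
  stored <- Filter(function(cf) relEnergy(cf) <= options@energyCutoff, stored)

  autos <- enumerateAutomorphisms(mol)
  symFn <- function(a, b) symmetryCorrectedRmsd(mol, a, b, autos)$rmsd
  pruned <- robustPrune(stored, d, symFn)

  log_("mol=%s rotors=%d total=%s tested=%d lowE=%d stored=%d diverse=%d rmsdEvals=%d",
       molTitle(mol), nr, format(N, scientific = FALSE), length(indices),
       nlow, length(stored), length(pruned), rmsdEvaluations(tree))

  list(ensemble = pruned,
       stats = list(rotors = nr, totalConformers = N,
                    tested = length(indices), lowEnergy = nlow,
                    stored = length(stored), diverse = length(pruned),
                    rmsdEvals = rmsdEvaluations(tree)))
}
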