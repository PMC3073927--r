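## MMFF94 evaluation behind the backend adapter ----------------------------
##
## Under torsion driving, bond stretch, angle bend, stretch-bend and
## out-of-plane terms are identical for every conformer of a molecule, so
## they are computed once; only torsion + van der Waals + electrostatics are
## re-evaluated per conformer.

#' Parameterise MMFF94 for one molecule
#'
#' Fails up front for molecules the forcefield cannot type (the classic
#' dataset filter). The constant bonded terms are evaluated once at the
#' input geometry.
#'
#' @param mol A [MoleculeGraph-class].
#' @param conf A [ConformerRecord-class] with the input 3D geometry.
#' @param variant `"MMFF94"` (default) or `"MMFF94s"`.
#' @return An [FFContext-class].
#' @export
setupForcefield <- function(mol, conf, variant = "MMFF94") {
  sdf <- .sdfBlock(mol, confCoords(conf), molTitle(mol))
  ans <- backendRequest(list(op = "load", sdf = sdf, variant = variant))
  if (!isTRUE(ans$typed)) {
    backendRequest(list(op = "release", id = ans$id))
    stop("MMFF94 cannot handle molecule '", molTitle(mol), "'")
  }
  if (ans$natoms != atomCount(mol)) {
    stop("backend atom count mismatch for '", molTitle(mol), "'")
  }
  new("FFContext", molId = as.integer(ans$id), sdf = sdf,
      natoms = as.integer(ans$natoms),
      constantTerms = as.numeric(ans$constant),
      inputCoords = confCoords(conf))
}

# Re-register the context after a backend restart.
.ctxId <- function(ctx) {
  ans <- tryCatch(
    backendRequest(list(op = "energies", id = ctx@molId, coords = list())),
    error = function(e) e)
  if (!inherits(ans, "error")) return(ctx@molId)
  ld <- backendRequest(list(op = "load", sdf = ctx@sdf))
  as.integer(ld$id)
}

# Batched energies for a list of coordinate matrices; returns list(total=,
# variable=) numeric vectors in kcal/mol.
.energiesBatch <- function(ctx, coordsList, chunk = 500L) {
  n <- length(coordsList)
  total <- numeric(n); variable <- numeric(n)
  id <- .ctxId(ctx)
  at <- 1L
  while (at <= n) {
    hi <- min(at + chunk - 1L, n)
    flat <- lapply(coordsList[at:hi], function(m) as.numeric(t(m)))
    ans <- backendRequest(list(op = "energies", id = id, coords = flat))
    total[at:hi] <- as.numeric(unlist(ans$total))
    variable[at:hi] <- as.numeric(unlist(ans$variable))
    at <- hi + 1L
  }
  list(total = total, variable = variable)
}

#' Variable part of the MMFF94 energy (torsion + van der Waals + electrostatic)
#'
#' @param ctx An [FFContext-class].
#' @param conf A [ConformerRecord-class] of the same molecule (or a list of
#'   them, in which case a numeric vector is returned).
#' @return kcal/mol.
#' @export
variableEnergy <- function(ctx, conf) {
  confs <- if (is(conf, "ConformerRecord")) list(conf) else conf
  coordsList <- lapply(confs, confCoords)
  e <- .energiesBatch(ctx, coordsList)$variable
  if (is(conf, "ConformerRecord")) e[[1]] else e
}

#' Total MMFF94 energy
#'
#' Equals `constantTerms(ctx) + variableEnergy(ctx, conf)` for torsion-driven
#' conformers of the context's molecule.
#'
#' @inheritParams variableEnergy
#' @return kcal/mol.
#' @export
totalEnergy <- function(ctx, conf) {
  confs <- if (is(conf, "ConformerRecord")) list(conf) else conf
  coordsList <- lapply(confs, confCoords)
  e <- .energiesBatch(ctx, coordsList)$total
  if (is(conf, "ConformerRecord")) e[[1]] else e
}

#' @describeIn FFContext-class Constant bonded-term energy (kcal/mol).
#' @param ctx An `FFContext`.
#' @export
constantTerms <- function(ctx) ctx@constantTerms

#' Short MMFF94 relaxation of an input structure
#'
#' Optional input preparation: a 200-step steepest-descent MMFF94
#' minimisation (via Open Babel's `obminimize`), as commonly applied to
#' generated 3D structures before torsion driving.
#'
#' @param mol A [MoleculeGraph-class].
#' @param conf A [ConformerRecord-class].
#' @param steps number of steepest-descent steps (default 200).
#' @return A relaxed [ConformerRecord-class].
#' @export
relaxStructure <- function(mol, conf, steps = 200L) {
  ob <- Sys.which("obminimize")
  if (!nzchar(ob)) stop("relaxStructure requires Open Babel's obminimize on the PATH")
  fin <- tempfile(fileext = ".sdf"); fout <- tempfile(fileext = ".sdf")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  cat(.sdfBlock(mol, confCoords(conf), molTitle(mol)), file = fin)
  res <- suppressWarnings(system2(ob, c("-ff", "MMFF94", "-sd", "-n", steps,
                                        "-osdf", fin),
                                  stdout = fout, stderr = FALSE))
  if (res != 0) stop("obminimize failed (exit ", res, ")")
  out <- readMolecules(fout)[[1]]
  ConformerRecord(confCoords(out$conf), relEnergy(conf), confIndex(conf))
}
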