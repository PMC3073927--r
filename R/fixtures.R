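## Embedded small-molecule fixtures ----------------------------------------

.fixtureNames <- c("butane", "ethylbenzene", "tert-butylbenzene", "biphenyl",
                   "para-difluorobenzene", "sulfone-analogue")

#' Path to a bundled fixture SDF
#'
#' @param name fixture name, see [makeFixture()].
#' @return path to the installed SDF file.
#' @export
fixturePath <- function(name) {
  if (!name %in% .fixtureNames) {
    stop("unknown fixture '", name, "'; available: ",
         paste(.fixtureNames, collapse = ", "))
  }
  p <- system.file("extdata", paste0(name, ".sdf"), package = "confabR")
  if (!nzchar(p)) stop("fixture file missing from installation: ", name)
  p
}

#' Deterministic embedded 3D structures for tests and examples
#'
#' Returns the SDF text of one of the bundled molecules. The alkane and
#' aryl fixtures are idealised geometries with exactly symmetric rings and
#' tert-butyl groups, so graph-symmetry-equivalent torsion settings give
#' numerically degenerate energies; `sulfone-analogue` (ethyl
#' (phenylsulfonyl)acetate, a synthetic stand-in for a phenyl sulfone with a
#' methylene ester arm) is a forcefield-relaxed geometry.
#'
#' @param name one of `"butane"`, `"ethylbenzene"`, `"tert-butylbenzene"`,
#'   `"biphenyl"`, `"para-difluorobenzene"`, `"sulfone-analogue"`.
#' @return SDF text (single record, `$$$$`-terminated).
#' @export
makeFixture <- function(name) {
  paste0(paste(readLines(fixturePath(name), warn = FALSE), collapse = "\n"), "\n")
}

#' Load a fixture as a (MoleculeGraph, ConformerRecord) pair
#'
#' Convenience wrapper around [readMolecules()] + [makeFixture()].
#'
#' @inheritParams makeFixture
#' @return `list(mol = MoleculeGraph, conf = ConformerRecord)`.
#' @export
loadFixture <- function(name) {
  readMolecules(fixturePath(name))[[1]]
}
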