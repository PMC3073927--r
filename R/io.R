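## SDF / MOL2 reading and SDF writing --------------------------------------

# molfile charge codes (atom block column): 0 none, 1..3 -> +3..+1, 5..7 -> -1..-3
.chargeFromCode <- function(code) {
  out <- integer(length(code))
  out[code == 1] <- 3L; out[code == 2] <- 2L; out[code == 3] <- 1L
  out[code == 5] <- -1L; out[code == 6] <- -2L; out[code == 7] <- -3L
  out
}
.codeFromCharge <- function(chg) {
  out <- integer(length(chg))
  out[chg == 3] <- 1L; out[chg == 2] <- 2L; out[chg == 1] <- 3L
  out[chg == -1] <- 5L; out[chg == -2] <- 6L; out[chg == -3] <- 7L
  out
}

# One parsed SDF record (ChemmineR SDF object + its raw text) -> MoleculeGraph
# + ConformerRecord
.moleculeFromSDF <- function(sdf, sdfText, recordNo) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  if (is.null(ab) || nrow(ab) == 0) {
    stop(sprintf("record %d: no atoms parsed", recordNo))
  }
  coords <- unname(as.matrix(ab[, 1:3, drop = FALSE]))
  storage.mode(coords) <- "double"
  if (all(abs(coords) < 1e-8)) {
    stop(sprintf("record %d: input must be 3D (all coordinates are zero)", recordNo))
  }
  elements <- sub("_.*$", "", rownames(ab))
  chgcode <- if ("C6" %in% colnames(ab)) as.integer(ab[, "C6"]) else integer(nrow(ab))
  charges <- .chargeFromCode(chgcode)
  # 'M  CHG' property lines supersede the legacy atom-block codes (ChemmineR
  # only reads the latter); when present, they reset all charges
  chgLines <- grep("^M  CHG", strsplit(sdfText, "\n")[[1]], value = TRUE)
  if (length(chgLines) > 0) {
    charges <- integer(nrow(ab))
    for (cl in chgLines) {
      v <- as.integer(strsplit(trimws(substring(cl, 7)), "\\s+")[[1]])
      nn <- v[1]
      for (k in seq_len(nn)) charges[v[2 * k]] <- v[2 * k + 1]
    }
  }

  if (is.null(bb) || nrow(bb) == 0) {
    bonds <- data.frame(i = integer(0), j = integer(0), order = integer(0),
                        aromatic = logical(0), inRing = logical(0))
  } else {
    ord <- as.integer(bb[, 3])
    arom <- ord == 4L           # order-4 bonds mark aromatic in some writers
    ord[arom] <- 1L
    bonds <- data.frame(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
                        order = ord, aromatic = arom, inRing = FALSE)
  }

  rings <- perceiveRings(nrow(ab), bonds)
  bonds$inRing <- rings$bondInRing
  arom <- perceiveAromaticity(sdfText)
  aromaticAtom <- seq_len(nrow(ab)) %in% arom$atoms
  if (nrow(arom$bonds) > 0 && nrow(bonds) > 0) {
    key <- function(i, j) paste(pmin(i, j), pmax(i, j))
    bonds$aromatic <- bonds$aromatic |
      key(bonds$i, bonds$j) %in% key(arom$bonds[, 1], arom$bonds[, 2])
  }

  hy <- perceiveHybridisation(elements, bonds, aromaticAtom)
  atoms <- data.frame(element = elements, charge = charges,
                      inRing = rings$atomInRing, hybrid = hy,
                      stringsAsFactors = FALSE)
  title <- ChemmineR::header(sdf)[["Molecule_Name"]]
  if (is.null(title) || is.na(title)) title <- ""
  mol <- new("MoleculeGraph", atoms = atoms, bonds = bonds,
             title = as.character(title),
             heavyIdx = which(elements != "H"))
  validObject(mol)
  list(mol = mol, conf = ConformerRecord(coords))
}

# Split a multi-record SDF file into per-record text blocks.
.splitSDF <- function(path) {
  lines <- readLines(path, warn = FALSE)
  ends <- grep("^\\$\\$\\$\\$\\s*$", lines)
  if (length(ends) == 0) ends <- length(lines)
  starts <- c(1, head(ends, -1) + 1)
  blocks <- mapply(function(s, e) paste0(paste(lines[s:e], collapse = "\n"), "\n"),
                   starts, ends, SIMPLIFY = TRUE)
  blocks[vapply(blocks, function(b) any(nzchar(trimws(strsplit(b, "\n")[[1]]))),
                logical(1))]
}

#' Read molecules with 3D coordinates from an SDF or MOL2 file
#'
#' Each record becomes a ([MoleculeGraph-class], [ConformerRecord-class])
#' pair. Hydrogens are retained; ring membership, aromaticity and
#' hybridisation are perceived on read. Records without 3D coordinates (all
#' zero) are rejected: torsion driving needs a real input geometry.
#'
#' @param path input file.
#' @param format `"sdf"` (V2000) or `"mol2"` (SYBYL; converted on the fly).
#' @return list of `list(mol = MoleculeGraph, conf = ConformerRecord)`.
#' @examples
#' \dontrun{
#' mols <- readMolecules(fixturePath("butane"))
#' mols[[1]]$mol
#' }
#' @export
readMolecules <- function(path, format = c("sdf", "mol2")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "mol2") {
    if (!requireNamespace("ChemmineOB", quietly = TRUE)) {
      stop("reading MOL2 requires the ChemmineOB package")
    }
    tmp <- tempfile(fileext = ".sdf")
    on.exit(unlink(tmp), add = TRUE)
    ChemmineOB::convertFormatFile("MOL2", "SDF", path, tmp)
    path <- tmp
  }
  blocks <- .splitSDF(path)
  if (length(blocks) == 0) stop("no records found in ", path)
  out <- vector("list", length(blocks))
  for (k in seq_along(blocks)) {
    sdfset <- tryCatch(
      suppressWarnings(ChemmineR::read.SDFset(ChemmineR::read.SDFstr(textConnection(blocks[[k]])))),
      error = function(e) NULL)
    if (is.null(sdfset) || length(sdfset) < 1) {
      stop(sprintf("record %d: could not be parsed as SDF", k))
    }
    out[[k]] <- .moleculeFromSDF(sdfset[[1]], blocks[[k]], k)
  }
  out
}

# Format one conformer as a V2000 molfile block (with $$$$ terminator).
.sdfBlock <- function(mol, coords, title, tags = NULL) {
  n <- atomCount(mol)
  b <- mol@bonds
  lines <- c(
    title,
    "  confabR",
    "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nrow(b))
  )
  at <- sprintf("%10.4f%10.4f%10.4f %-3s 0%3d  0  0  0  0  0  0  0  0  0  0",
                coords[, 1], coords[, 2], coords[, 3],
                mol@atoms$element, .codeFromCharge(mol@atoms$charge))
  bd <- sprintf("%3d%3d%3d  0  0  0  0", b$i, b$j, b$order)
  lines <- c(lines, at, bd)
  chg <- which(mol@atoms$charge != 0)
  if (length(chg) > 0) {
    for (start in seq(1, length(chg), by = 8)) {
      idx <- chg[start:min(start + 7, length(chg))]
      lines <- c(lines, paste0("M  CHG", sprintf("%3d", length(idx)),
                               paste0(sprintf("%4d%4d", idx, mol@atoms$charge[idx]),
                                      collapse = "")))
    }
  }
  lines <- c(lines, "M  END")
  for (nm in names(tags)) {
    lines <- c(lines, sprintf("> <%s>", nm), tags[[nm]], "")
  }
  paste0(paste(lines, collapse = "\n"), "\n$$$$\n")
}

#' Write a conformer ensemble as a multi-record SDF file
#'
#' One record per conformer; the relative energy (kcal/mol, 4 decimals) is
#' written as the SD tag `Energy_rel_kcalmol` and the molecule title gains a
#' `" conformer <k>"` suffix.
#'
#' @param path output file.
#' @param mol the parent [MoleculeGraph-class].
#' @param ensemble non-empty list of [ConformerRecord-class] objects.
#' @return invisibly, the number of records written.
#' @export
writeConformers <- function(path, mol, ensemble) {
  if (length(ensemble) == 0) stop("ensemble must be non-empty")
  con <- tryCatch(file(path, "w"), error = function(e) {
    stop("cannot write to ", path, ": ", conditionMessage(e))
  })
  on.exit(close(con))
  for (k in seq_along(ensemble)) {
    conf <- ensemble[[k]]
    stopifnot(nrow(confCoords(conf)) == atomCount(mol))
    block <- .sdfBlock(
      mol, confCoords(conf),
      title = sprintf("%s conformer %d", molTitle(mol), k),
      tags = list(Energy_rel_kcalmol = sprintf("%.4f", relEnergy(conf)))
    )
    cat(block, file = con, sep = "")
  }
  invisible(length(ensemble))
}
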