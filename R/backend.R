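## Persistent chemistry backend (RDKit via python) -------------------------
##
## A single python process per R session serves MMFF94 energies, SMARTS
## matches and aromaticity perception over a line-oriented JSON protocol.
## Starting it costs one rdkit import; every later request is milliseconds.

.confab <- new.env(parent = emptyenv())
.confab$proc <- NULL
.confab$buf <- ""

backendScript <- function() {
  p <- system.file("python", "chem_backend.py", package = "confabR")
  if (!nzchar(p)) {
    # during development (pkgload) system.file resolves inst/ already
    p <- system.file("inst", "python", "chem_backend.py", package = "confabR")
  }
  if (!nzchar(p)) stop("backend script not found in the installed package")
  p
}

backendAlive <- function() {
  !is.null(.confab$proc) && .confab$proc$is_alive()
}

startBackend <- function() {
  python <- Sys.getenv("CONFABR_PYTHON", unset = Sys.which("python"))
  if (!nzchar(python)) stop("no 'python' found on the PATH; the MMFF94/SMARTS ",
                            "backend requires python with rdkit")
  proc <- processx::process$new(python, c("-u", backendScript()),
                                stdin = "|", stdout = "|", stderr = "|")
  .confab$proc <- proc
  .confab$buf <- ""
  # handshake (also forces the rdkit import so failures surface here)
  ans <- tryCatch(backendRequest(list(op = "ping"), timeout = 120),
                  error = function(e) e)
  if (inherits(ans, "error") || !isTRUE(ans$pong)) {
    err <- tryCatch(paste(proc$read_error_lines(), collapse = "\n"),
                    error = function(e) "")
    stopBackend()
    stop("could not start the chemistry backend (python + rdkit): ", err)
  }
  invisible(proc)
}

stopBackend <- function() {
  if (!is.null(.confab$proc)) {
    try(.confab$proc$kill(), silent = TRUE)
    .confab$proc <- NULL
  }
  invisible(NULL)
}

ensureBackend <- function() {
  if (!backendAlive()) startBackend()
  invisible(NULL)
}

readBackendLine <- function(proc, timeout) {
  deadline <- Sys.time() + timeout
  repeat {
    nl <- regexpr("\n", .confab$buf, fixed = TRUE)
    if (nl > 0) {
      line <- substr(.confab$buf, 1, nl - 1)
      .confab$buf <- substr(.confab$buf, nl + 1, nchar(.confab$buf))
      return(line)
    }
    if (!proc$is_alive() && !proc$is_incomplete_output()) {
      stop("chemistry backend exited unexpectedly: ",
           paste(tail(proc$read_error_lines(), 5), collapse = "; "))
    }
    proc$poll_io(200)
    chunk <- proc$read_output()
    if (nzchar(chunk)) .confab$buf <- paste0(.confab$buf, chunk)
    if (Sys.time() > deadline) stop("chemistry backend timed out")
  }
}

backendRequest <- function(req, timeout = 600) {
  ensureBackend()
  proc <- .confab$proc
  line <- jsonlite::toJSON(req, auto_unbox = TRUE, digits = NA)
  proc$write_input(paste0(line, "\n"))
  ans <- jsonlite::fromJSON(readBackendLine(proc, timeout),
                            simplifyVector = TRUE, simplifyMatrix = FALSE,
                            simplifyDataFrame = FALSE)
  if (!is.null(ans$error)) stop("chemistry backend error: ", ans$error)
  ans
}

## reg.finalizer-friendly shutdown
.onUnload <- function(libpath) {
  stopBackend()
  library.dynam.unload("confabR", libpath)
}
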