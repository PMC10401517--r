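#' @keywords internal
"_PACKAGE"

#' @importFrom stats median sd setNames rnorm runif
#' @importFrom utils read.csv write.csv head combn
NULL

# rbind a list of data.frames, ignoring NULLs; NULL when nothing remains
rbind_rows <- function(rows) {
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0) return(NULL)
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

# Locate the python interpreter used for molecular primitives. The package
# expects an interpreter named "python" (or "python3") on PATH with RDKit
# importable; override with options(sascliffs.python = "/path/to/python").
bridge_python_bin <- function() {
  opt <- getOption("sascliffs.python", NULL)
  if (!is.null(opt)) return(opt)
  for (cand in c("python", "python3")) {
    hit <- Sys.which(cand)
    if (nzchar(hit)) return(unname(hit))
  }
  stop("sascliffs needs a 'python' interpreter with RDKit on PATH", call. = FALSE)
}

bridge_script_path <- function() {
  p <- system.file("python", "chem_bridge.py", package = "sascliffs")
  if (!nzchar(p)) stop("chem_bridge.py not found; is sascliffs installed correctly?",
                       call. = FALSE)
  p
}

# Run one batched bridge op. `request` is converted to JSON (scalars unboxed;
# wrap vectors that must stay arrays in I()). Returns the parsed `result`.
chem_bridge <- function(op, request) {
  infile <- tempfile("sascliffs_req_", fileext = ".json")
  outfile <- tempfile("sascliffs_res_", fileext = ".json")
  errfile <- tempfile("sascliffs_err_", fileext = ".txt")
  on.exit(unlink(c(infile, outfile, errfile)), add = TRUE)
  jsonlite::write_json(request, infile, auto_unbox = TRUE, digits = NA,
                       null = "null")
  status <- suppressWarnings(system2(
    bridge_python_bin(),
    c(shQuote(bridge_script_path()), op, shQuote(infile), shQuote(outfile)),
    stdout = FALSE, stderr = errfile))
  if (!identical(status, 0L) || !file.exists(outfile)) {
    err <- if (file.exists(errfile)) paste(readLines(errfile, warn = FALSE),
                                           collapse = "\n") else ""
    stop("chemistry bridge call '", op, "' failed (exit ", status, "): ", err,
         call. = FALSE)
  }
  res <- jsonlite::fromJSON(outfile, simplifyVector = FALSE)
  if (!isTRUE(res$ok)) {
    stop("chemistry bridge op '", op, "' reported: ", res$error, call. = FALSE)
  }
  res$result
}
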