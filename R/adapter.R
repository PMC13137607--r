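# Bridge to the Python/RDKit typing adapter. A single request/response JSON
# protocol; results are memoised per session so repeated parameterization of
# the same structures costs one process spawn.

the <- new.env(parent = emptyenv())

adapter_path <- function() {
  path <- system.file("python", "mmff_adapter.py", package = "ffguide")
  if (!nzchar(path)) {
    stop("bundled adapter script not found; is ffguide installed?")
  }
  path
}

python_binary <- function() {
  bin <- Sys.which("python")
  if (!nzchar(bin)) bin <- Sys.which("python3")
  if (!nzchar(bin)) {
    stop("no 'python' interpreter on PATH; the MMFF94 typing adapter ",
         "requires Python with rdkit")
  }
  unname(bin)
}

#' Call the bundled RDKit adapter
#'
#' Low-level plumbing used by [parameterize()], [make_fixture_set()],
#' [mmff_reference_energy()] and friends. Exposed mainly for debugging.
#'
#' @param req A named list describing the request (must contain `mode`).
#' @param cache Memoise the response for identical requests in this session.
#' @return The `result` component of the adapter response.
#' @keywords internal
adapter_call <- function(req, cache = TRUE) {
  key <- rlang::hash(req)
  if (cache && !is.null(the$adapter_cache[[key]])) {
    return(the$adapter_cache[[key]])
  }
  infile <- tempfile(fileext = ".json")
  outfile <- tempfile(fileext = ".json")
  on.exit(unlink(c(infile, outfile)), add = TRUE)
  jsonlite::write_json(req, infile, auto_unbox = TRUE, digits = NA,
                       null = "null")
  status <- system2(python_binary(), shQuote(adapter_path()),
                    stdin = infile, stdout = outfile, stderr = FALSE)
  if (status != 0L) {
    stop("MMFF94 typing adapter exited with status ", status)
  }
  res <- jsonlite::read_json(outfile)
  if (!isTRUE(res$ok)) {
    stop("MMFF94 typing adapter error: ", res$error)
  }
  if (cache) {
    if (is.null(the$adapter_cache)) the$adapter_cache <- new.env(parent = emptyenv())
    the$adapter_cache[[key]] <- res$result
  }
  res$result
}
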