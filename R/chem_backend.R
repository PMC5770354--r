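# Chemistry backend: all structure handling (canonicalization, desalting,
# descriptor and fingerprint calculation, SDF parsing) runs through one
# RDKit process per batch, via the bridge script shipped in inst/python/.
# A single toolkit guarantees a consistent canonical-SMILES dialect across
# the whole pipeline.

chem_python <- function() {
  py <- getOption("autoqsar.python", Sys.which("python"))
  if (!nzchar(py))
    config_error("no 'python' interpreter with RDKit found on the PATH")
  py
}

chem_bridge_script <- function() {
  path <- system.file("python", "chem_bridge.py", package = "autoqsar")
  if (!nzchar(path)) {
    # during development (pkgload) inst/ may be the source tree
    path <- system.file("inst", "python", "chem_bridge.py", package = "autoqsar")
  }
  if (!nzchar(path)) config_error("chem_bridge.py not found in the installed package")
  path
}

run_chem_bridge <- function(cmd, input = NULL, args_json = NULL,
                            input_is_path = FALSE) {
  outfile <- tempfile(fileext = ".csv")
  on.exit(unlink(outfile), add = TRUE)
  argv <- c(chem_bridge_script(), cmd)
  if (cmd == "version") {
    argv <- c(argv, outfile)
  } else {
    if (input_is_path) {
      infile <- input
    } else {
      infile <- tempfile(fileext = ".tsv")
      on.exit(unlink(infile), add = TRUE)
      writeLines(input, infile)
    }
    argv <- c(argv, infile, outfile)
    if (!is.null(args_json)) argv <- c(argv, args_json)
  }
  status <- system2(chem_python(), shQuote(argv), stdout = FALSE, stderr = "")
  if (status != 0L)
    io_error(sprintf("chemistry backend failed (command '%s', exit %d)",
                     cmd, status))
  if (cmd == "version") jsonlite::fromJSON(outfile)
  else utils::read.csv(outfile, stringsAsFactors = FALSE,
                       colClasses = "character")
}

#' Chemistry toolkit version information
#'
#' Reports the backend toolkit and version used for canonicalization,
#' descriptors and fingerprints; recorded in every run manifest so feature
#' matrices are reproducible.
#'
#' @return A list with \code{toolkit}, \code{version},
#'   \code{n_descriptors}.
#' @export
chem_toolkit_version <- function() {
  if (is.null(.chem_cache$version))
    .chem_cache$version <- run_chem_bridge("version")
  .chem_cache$version
}

.chem_cache <- new.env(parent = emptyenv())

# Batch canonicalization: returns data.frame(compound_id, canonical_smiles,
# status, reason) aligned with the input.
canonicalize_batch <- function(ids, smiles) {
  stopifnot(length(ids) == length(smiles))
  lines <- paste(ids, smiles, sep = "\t")
  out <- run_chem_bridge("canonicalize", lines)
  if (nrow(out) != length(ids))
    io_error("chemistry backend returned a misaligned canonicalization table")
  out
}
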