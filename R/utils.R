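# Internal helpers: structured conditions, seeded evaluation, logging.

abort_aq <- function(msg, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "autoqsar_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

config_error  <- function(msg) abort_aq(msg, "autoqsar_config_error")
io_error      <- function(msg) abort_aq(msg, "autoqsar_io_error")
domain_error  <- function(msg) abort_aq(msg, "autoqsar_domain_error")
too_small_error <- function(msg) abort_aq(msg, "autoqsar_too_small_error")
empty_dataset_error <- function(msg) abort_aq(msg, "autoqsar_empty_dataset_error")
alignment_error <- function(msg) abort_aq(msg, "autoqsar_alignment_error")
consistency_error <- function(msg) abort_aq(msg, "autoqsar_consistency_error")

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random stream.
with_seed <- function(seed, code) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

aq_log <- function(stage, ..., file = NULL) {
  line <- paste0("[", stage, "] ", paste0(..., collapse = ""))
  message(line)
  if (!is.null(file)) cat(line, "\n", file = file, append = TRUE, sep = "")
  invisible(line)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
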