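#' Parse a compound-activity input file
#'
#' Reads compound records from CSV (header row with columns
#' \code{compound_id}, \code{smiles}, \code{activity_type},
#' \code{activity_value} and optional \code{year}), from a SMILES file (one
#' structure per line, optional whitespace-separated identifier), or from a
#' V2000 SDF whose tags carry the activity fields. Unparsable activity
#' values become missing values here; dropping them is the curation
#' stage's job.
#'
#' @param path Input file path.
#' @param format \code{"csv"}, \code{"smi"} or \code{"sdf"}; the default
#'   infers it from the file extension.
#' @return A data.frame of compound records with columns
#'   \code{compound_id}, \code{smiles}, \code{activity_type},
#'   \code{activity_value}, \code{year}.
#' @export
parse_input <- function(path, format = c("auto", "csv", "smi", "sdf")) {
  format <- match.arg(format)
  if (!file.exists(path)) io_error(paste0("input file not found: ", path))
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", smi = "smi", txt = "smi", sdf = "sdf",
                     config_error(paste0("cannot infer input format from extension: ", ext)))
  }
  switch(format,
    csv = parse_csv_records(path),
    smi = parse_smi_records(path),
    sdf = parse_sdf_records(path))
}

parse_csv_records <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  required <- c("compound_id", "smiles", "activity_type", "activity_value")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L)
    config_error(paste0("input CSV lacks required column(s): ",
                        paste(missing_cols, collapse = ", ")))
  as_compound_records(
    compound_id = df$compound_id, smiles = df$smiles,
    activity_type = df$activity_type, activity_value = df$activity_value,
    year = if ("year" %in% names(df)) df$year else NA_character_)
}

parse_smi_records <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "[[:space:]]+")
  smiles <- vapply(parts, `[`, character(1), 1L)
  ids <- vapply(seq_along(parts), function(i)
    if (length(parts[[i]]) > 1L) parts[[i]][2L] else sprintf("MOL_%d", i),
    character(1))
  as_compound_records(compound_id = ids, smiles = smiles,
                      activity_type = NA_character_,
                      activity_value = NA_character_,
                      year = NA_character_)
}

parse_sdf_records <- function(path) {
  out <- run_chem_bridge("parse_sdf", path, input_is_path = TRUE)
  as_compound_records(compound_id = out$compound_id, smiles = out$smiles,
                      activity_type = out$activity_type,
                      activity_value = out$activity_value, year = out$year)
}

# Normalize raw fields into the record schema; activity values that do not
# parse as positive numbers are kept as NA, never silently coerced to 0.
as_compound_records <- function(compound_id, smiles, activity_type,
                                activity_value, year) {
  n <- length(compound_id)
  value <- suppressWarnings(as.numeric(activity_value))
  value[!is.finite(value)] <- NA_real_
  yr <- suppressWarnings(as.integer(year))
  df <- data.frame(
    compound_id = as.character(compound_id),
    smiles = as.character(smiles),
    activity_type = rep_len(as.character(activity_type), n),
    activity_value = value,
    year = rep_len(yr, n),
    stringsAsFactors = FALSE)
  if (any(!nzchar(df$compound_id) | is.na(df$compound_id)))
    config_error("every record needs a non-empty compound_id")
  df
}
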