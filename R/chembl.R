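#' Build a bioactivity target query
#'
#' @param uniprot_id UniProt accession (6-10 alphanumeric characters) or a
#'   ChEMBL target identifier (\code{CHEMBL...}).
#' @param activity_type Requested activity label (e.g. \code{"Ki"},
#'   \code{"IC50"}).
#' @param organism_filter Optional organism label.
#' @return An object of class \code{target_query}.
#' @export
target_query <- function(uniprot_id, activity_type,
                         organism_filter = NULL) {
  if (!grepl("^[A-Za-z0-9]{6,10}$", uniprot_id) &&
      !grepl("^CHEMBL[0-9]+$", uniprot_id))
    config_error(paste0("'", uniprot_id,
                        "' is neither a UniProt accession nor a ChEMBL target id"))
  if (!nzchar(activity_type)) config_error("activity_type must be non-empty")
  structure(list(uniprot_id = uniprot_id, activity_type = activity_type,
                 organism_filter = organism_filter),
            class = "target_query")
}

#' Fetch a bioactivity listing for a target
#'
#' Resolves the query against a ChEMBL-style REST activity endpoint, or —
#' the path used in tests and offline runs — reads a saved JSON response
#' from disk. The payload is returned untouched; all network use of the
#' pipeline is isolated here.
#'
#' @param query A \code{target_query}.
#' @param endpoint A URL (\code{http(s)://...}) or the path of a saved
#'   JSON response.
#' @return The parsed activity listing (a list of activity entries).
#' @export
fetch_bioactivities <- function(query, endpoint) {
  stopifnot(inherits(query, "target_query"))
  if (grepl("^https?://", endpoint)) {
    payload <- tryCatch(
      jsonlite::fromJSON(endpoint, simplifyVector = FALSE),
      error = function(e) io_error(paste0(
        "could not reach bioactivity endpoint ", endpoint,
        " (retryable): ", conditionMessage(e))))
  } else {
    if (!file.exists(endpoint))
      io_error(paste0("bioactivity fixture not found: ", endpoint))
    payload <- jsonlite::fromJSON(endpoint, simplifyVector = FALSE)
  }
  if (is.list(payload) && !is.null(payload$activities))
    payload <- payload$activities
  if (!is.list(payload))
    io_error("bioactivity payload is not an activity listing")
  payload
}

#' Parse a ChEMBL-style activity payload into compound records
#'
#' Maps \code{molecule_chembl_id} to \code{compound_id},
#' \code{canonical_smiles} to \code{smiles}, \code{standard_type} to
#' \code{activity_type}, \code{standard_value} to \code{activity_value} and
#' the document year to \code{year}. Entries missing a structure or value
#' become records with absent fields (curation drops them); entries whose
#' standard units are not nM are skipped and logged, since the downstream
#' activity scaling assumes a fixed nM concentration scale. Malformed
#' entries raise a parse error in strict mode and are logged skips
#' otherwise.
#'
#' @param payload Activity listing from \code{\link{fetch_bioactivities}}.
#' @param strict Abort on the first malformed entry (default \code{FALSE}).
#' @return A data.frame of compound records; attribute \code{"skips"}
#'   holds a data.frame of skipped entry indices and reasons so counts
#'   reconcile with the payload size.
#' @export
parse_chembl_payload <- function(payload, strict = FALSE) {
  rows <- list()
  skips <- list()
  for (i in seq_along(payload)) {
    e <- payload[[i]]
    if (!is.list(e) || is.null(e$molecule_chembl_id)) {
      if (strict)
        abort_aq(sprintf("malformed activity entry at index %d", i),
                 "autoqsar_parse_error")
      skips[[length(skips) + 1L]] <- data.frame(
        index = i, reason = "malformed_entry", stringsAsFactors = FALSE)
      next
    }
    units <- e$standard_units %||% NA_character_
    if (!is.na(units) && !identical(units, "nM")) {
      skips[[length(skips) + 1L]] <- data.frame(
        index = i, reason = paste0("units_not_nM:", units),
        stringsAsFactors = FALSE)
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      compound_id = as.character(e$molecule_chembl_id),
      smiles = as.character(e$canonical_smiles %||% NA_character_),
      activity_type = as.character(e$standard_type %||% NA_character_),
      activity_value = suppressWarnings(
        as.numeric(e$standard_value %||% NA_character_)),
      year = suppressWarnings(
        as.integer(e$document_year %||% e$year %||% NA_integer_)),
      stringsAsFactors = FALSE)
  }
  records <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(compound_id = character(0), smiles = character(0),
               activity_type = character(0), activity_value = numeric(0),
               year = integer(0), stringsAsFactors = FALSE)
  attr(records, "skips") <- if (length(skips) > 0L) do.call(rbind, skips) else
    data.frame(index = integer(0), reason = character(0),
               stringsAsFactors = FALSE)
  records
}
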