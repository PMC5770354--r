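#' Canonicalize a structure and strip salt/solvent fragments
#'
#' Replaces each SMILES by the canonical form of its largest organic
#' fragment (most heavy atoms among fragments containing carbon), the
#' standard parent-extraction convention for salt forms. Unparsable
#' structures and structures without an organic fragment are returned as
#' rejections with a reason code rather than errors, so batch curation can
#' account for them.
#'
#' @param smiles Character vector of SMILES strings.
#' @param compound_id Optional identifiers (defaults to the input strings).
#' @return A data.frame with columns \code{compound_id}, \code{smiles}
#'   (input), \code{canonical_smiles}, \code{status} (\code{"ok"} or
#'   \code{"rejected"}), \code{reason} (\code{"invalid_structure"} or
#'   \code{"inorganic_only"}).
#' @export
canonicalize_and_desalt <- function(smiles, compound_id = smiles) {
  if (any(!nzchar(smiles) | is.na(smiles)))
    config_error("empty SMILES cannot be canonicalized")
  out <- canonicalize_batch(compound_id, smiles)
  data.frame(compound_id = as.character(compound_id),
             smiles = as.character(smiles),
             canonical_smiles = out$canonical_smiles,
             status = out$status, reason = out$reason,
             stringsAsFactors = FALSE)
}

#' Curate compound-activity records
#'
#' Applies the curation rules in order: keep only the requested activity
#' type; drop records with absent or non-positive activity values (a
#' positive value is required for the log scaling later); canonicalize and
#' desalt structures, rejecting unparsable ones; deduplicate by canonical
#' structure. Among duplicates the record with the most recent year wins;
#' when years tie or are absent, the record whose activity is the median of
#' the duplicate group is kept (lower original index on even-sized ties).
#' Every dropped record is accounted for in the curation log.
#'
#' @param records Data.frame of compound records as returned by
#'   \code{\link{parse_input}} or \code{\link{parse_chembl_payload}}.
#' @param requested_activity_type Activity type to retain (e.g.
#'   \code{"Ki"}).
#' @return An object of class \code{curated_dataset}: \code{records} (with
#'   a \code{canonical_smiles} column) and \code{curation_log} (per-rule
#'   counts reconciling input and output sizes).
#' @export
curate <- function(records, requested_activity_type) {
  if (!nzchar(requested_activity_type))
    config_error("requested_activity_type must be non-empty")
  required <- c("compound_id", "smiles", "activity_type", "activity_value")
  if (!all(required %in% names(records)))
    config_error("records lack required columns")
  if (!"year" %in% names(records)) records$year <- NA_integer_
  n_in <- nrow(records)

  keep_type <- !is.na(records$activity_type) &
    records$activity_type == requested_activity_type
  n_type <- sum(!keep_type)
  records <- records[keep_type, , drop = FALSE]

  keep_val <- !is.na(records$activity_value) & records$activity_value > 0
  n_missing <- sum(!keep_val)
  records <- records[keep_val, , drop = FALSE]

  n_invalid <- 0L
  n_desalted <- 0L
  if (nrow(records) > 0L) {
    can <- canonicalize_and_desalt(records$smiles, records$compound_id)
    ok <- can$status == "ok"
    n_invalid <- sum(!ok)
    n_desalted <- sum(ok & grepl(".", can$smiles, fixed = TRUE))
    records <- records[ok, , drop = FALSE]
    records$canonical_smiles <- can$canonical_smiles[ok]
  } else {
    records$canonical_smiles <- character(0)
  }

  n_dedup <- 0L
  if (nrow(records) > 0L) {
    keep_idx <- unlist(lapply(
      split(seq_len(nrow(records)), records$canonical_smiles),
      function(idx) resolve_duplicates(records[idx, , drop = FALSE], idx)))
    n_dedup <- nrow(records) - length(keep_idx)
    records <- records[sort(keep_idx), , drop = FALSE]
  }
  rownames(records) <- NULL

  log <- data.frame(
    rule = c("input", "dropped_activity_type", "dropped_missing_value",
             "rejected_structure", "desalted", "deduplicated", "kept"),
    count = c(n_in, n_type, n_missing, n_invalid, n_desalted, n_dedup,
              nrow(records)),
    stringsAsFactors = FALSE)

  if (nrow(records) == 0L)
    empty_dataset_error(paste0(
      "no records survived curation for activity type '",
      requested_activity_type,
      "' - check the activity-type filter and input quality"))

  structure(list(records = records, curation_log = log),
            class = "curated_dataset")
}

# One duplicate group: unique most recent year wins; otherwise the
# median-activity representative among the most recent candidates
# (both middle records eligible on even sizes; lower original index wins).
resolve_duplicates <- function(group, idx) {
  if (nrow(group) == 1L) return(idx)
  yrs <- group$year
  if (all(is.na(yrs))) {
    cand <- seq_len(nrow(group))
  } else {
    cand <- which(!is.na(yrs) & yrs == max(yrs, na.rm = TRUE))
    if (length(cand) == 1L) return(idx[cand])
  }
  act <- group$activity_value[cand]
  ord <- order(act)
  g <- length(cand)
  mids <- if (g %% 2L == 1L) ord[(g + 1L) %/% 2L] else ord[c(g %/% 2L, g %/% 2L + 1L)]
  idx[cand[mids[which.min(idx[cand[mids]])]]]
}

#' @export
print.curated_dataset <- function(x, ...) {
  cat(sprintf("curated_dataset: %d records\n", nrow(x$records)))
  print(x$curation_log, row.names = FALSE)
  invisible(x)
}

#' Write the curation log as CSV
#'
#' @param x A \code{curated_dataset}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_curation_log <- function(x, path) {
  stopifnot(inherits(x, "curated_dataset"))
  utils::write.csv(x$curation_log, path, row.names = FALSE)
  invisible(path)
}
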