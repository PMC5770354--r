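#' Fingerprint specification
#'
#' Nine fingerprint families are supported: \code{morgan} (circular,
#' ECFP-like), \code{feat_morgan} (circular over pharmacophoric feature
#' invariants, FCFP-like), \code{atom_pair}, \code{torsion} (topological
#' torsions), \code{path} (path-based, daylight-like), \code{avalon},
#' \code{layered}, \code{maccs} (166 structural keys, fixed width) and
#' \code{pattern} (substructure screening).
#'
#' @param kind One of the nine fingerprint kinds.
#' @param n_bits Folded bit width (default 1024, the conventional ECFP4
#'   setting); ignored for \code{maccs}, whose key length is fixed.
#' @param radius Neighbourhood radius for the Morgan variants (default 2).
#' @return An object of class \code{fingerprint_spec}.
#' @export
fingerprint_spec <- function(kind = c("morgan", "feat_morgan", "atom_pair",
                                      "torsion", "path", "avalon",
                                      "layered", "maccs", "pattern"),
                             n_bits = 1024L, radius = 2L) {
  kind <- match.arg(kind)
  if (n_bits < 1L) config_error("n_bits must be positive")
  if (radius < 0L) config_error("radius must be non-negative")
  if (kind == "maccs" && !missing(n_bits))
    warning("maccs keys have a fixed length; n_bits is ignored",
            call. = FALSE)
  structure(list(kind = kind, n_bits = as.integer(n_bits),
                 radius = as.integer(radius)),
            class = "fingerprint_spec")
}

# Named canonical SMILES in, or a curated_dataset's records.
featurize_ids <- function(structures) {
  if (is.null(names(structures)))
    stats::setNames(structures, structures) else structures
}

#' Compute physicochemical descriptors
#'
#' One row per structure over the backend toolkit's full standard
#' descriptor list (about 210 descriptors covering constitutional,
#' topological, electronic and lipophilicity properties). Structures
#' yielding any non-finite descriptor are rejected with a reason and
#' reported in the \code{"rejections"} attribute rather than producing
#' missing entries.
#'
#' @param structures Character vector of canonical SMILES, optionally
#'   named by compound id.
#' @return A \code{feature_matrix} of descriptor columns (prefixed
#'   \code{desc_}); attribute \code{"rejections"} lists rejected
#'   structures and reasons.
#' @export
compute_descriptors <- function(structures) {
  structures <- featurize_ids(structures)
  out <- run_chem_bridge("descriptors",
                         paste(names(structures), structures, sep = "\t"))
  ok <- out$status == "ok"
  rejections <- data.frame(compound_id = out$compound_id[!ok],
                           reason = out$status[!ok],
                           stringsAsFactors = FALSE)
  if (!any(ok))
    empty_dataset_error("no structure yielded a complete descriptor row")
  vals <- as.matrix(out[ok, -(1:2), drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- out$compound_id[ok]
  colnames(vals) <- paste0("desc_", colnames(vals))
  fm <- feature_matrix(vals, "descriptor")
  attr(fm, "rejections") <- rejections
  fm
}

#' Compute a molecular fingerprint block
#'
#' Binary n x n_bits matrix for one fingerprint kind; deterministic per
#' structure. Column names carry the kind as a prefix so blocks stay
#' disjoint when merged.
#'
#' @param structures Character vector of canonical SMILES, optionally
#'   named by compound id.
#' @param spec A \code{\link{fingerprint_spec}}.
#' @return A \code{feature_matrix} of fingerprint bits; attribute
#'   \code{"rejections"} as in \code{\link{compute_descriptors}}.
#' @export
compute_fingerprints <- function(structures, spec = fingerprint_spec()) {
  if (!inherits(spec, "fingerprint_spec"))
    config_error("spec must be a fingerprint_spec")
  structures <- featurize_ids(structures)
  out <- run_chem_bridge(
    "fingerprints", paste(names(structures), structures, sep = "\t"),
    args_json = jsonlite::toJSON(
      list(kind = spec$kind, n_bits = spec$n_bits, radius = spec$radius),
      auto_unbox = TRUE))
  ok <- out$status == "ok"
  rejections <- data.frame(compound_id = out$compound_id[!ok],
                           reason = out$status[!ok],
                           stringsAsFactors = FALSE)
  if (!any(ok))
    empty_dataset_error("no structure yielded a fingerprint")
  vals <- as.matrix(out[ok, -(1:2), drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- out$compound_id[ok]
  colnames(vals) <- sub("^bit_", paste0(spec$kind, "_"), colnames(vals))
  fm <- feature_matrix(vals, "fingerprint")
  attr(fm, "rejections") <- rejections
  fm
}

#' Merge descriptor and fingerprint blocks into one feature matrix
#'
#' Column-wise concatenation of blocks sharing identical row order.
#' Constant (zero-variance) columns are removed here — before any scaling,
#' whose denominator they would break — and recorded in the
#' \code{"removed_constant"} attribute.
#'
#' @param blocks List of \code{feature_matrix} objects with identical
#'   \code{row_ids} in identical order and disjoint column names.
#' @return A merged \code{feature_matrix}.
#' @export
merge_feature_blocks <- function(blocks) {
  if (length(blocks) < 1L) config_error("no feature blocks to merge")
  stopifnot(all(vapply(blocks, inherits, logical(1), "feature_matrix")))
  ids <- rownames(blocks[[1L]]$values)
  for (b in blocks)
    if (!identical(rownames(b$values), ids))
      alignment_error("feature blocks disagree on row identifiers or order")
  all_names <- unlist(lapply(blocks, function(b) colnames(b$values)))
  if (anyDuplicated(all_names))
    alignment_error("feature blocks have overlapping column names")
  vals <- do.call(cbind, lapply(blocks, function(b) b$values))
  kinds <- unlist(lapply(blocks, function(b) b$column_kind))
  keep <- apply(vals, 2L, function(col) max(col) > min(col))
  fm <- feature_matrix(vals[, keep, drop = FALSE], unname(kinds[keep]))
  attr(fm, "removed_constant") <- colnames(vals)[!keep]
  fm
}
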