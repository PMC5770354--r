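#' Construct a feature matrix
#'
#' The pipeline's central container: an n x p numeric matrix of molecular
#' features with compound identifiers as row names and a per-column tag
#' distinguishing physicochemical descriptors from fingerprint bits.
#'
#' @param values Numeric matrix with unique row and column names and no
#'   missing entries.
#' @param column_kind Character vector, one of \code{"descriptor"} or
#'   \code{"fingerprint"} per column (recycled if length 1). Fingerprint
#'   columns must contain only 0/1 values.
#' @return An object of class \code{feature_matrix}: a list with elements
#'   \code{values} and \code{column_kind}.
#' @export
feature_matrix <- function(values, column_kind = "descriptor") {
  values <- as.matrix(values)
  if (!is.numeric(values)) config_error("feature matrix values must be numeric")
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)))
    config_error("feature matrix requires unique row identifiers (rownames)")
  if (is.null(colnames(values)) || anyDuplicated(colnames(values)))
    config_error("feature matrix requires unique column names")
  if (anyNA(values) || any(!is.finite(values)))
    config_error("feature matrix must not contain missing or non-finite entries")
  if (length(column_kind) == 1L) column_kind <- rep(column_kind, ncol(values))
  if (length(column_kind) != ncol(values))
    alignment_error("column_kind length does not match column count")
  if (!all(column_kind %in% c("descriptor", "fingerprint")))
    config_error("column_kind entries must be 'descriptor' or 'fingerprint'")
  names(column_kind) <- colnames(values)
  fp <- column_kind == "fingerprint"
  if (any(fp) && !all(values[, fp, drop = FALSE] %in% c(0, 1)))
    config_error("fingerprint columns must be binary (0/1)")
  structure(list(values = values, column_kind = column_kind),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf(
    "feature_matrix: %d compounds x %d features (%d descriptor, %d fingerprint)\n",
    nrow(x$values), ncol(x$values),
    sum(x$column_kind == "descriptor"), sum(x$column_kind == "fingerprint")))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

#' @export
as.matrix.feature_matrix <- function(x, ...) x$values

# Accept either a feature_matrix or a plain numeric matrix.
fm_values <- function(x) {
  if (inherits(x, "feature_matrix")) x$values else as.matrix(x)
}

# Row/column subset preserving column kinds.
fm_subset <- function(x, rows = NULL, cols = NULL) {
  stopifnot(inherits(x, "feature_matrix"))
  v <- x$values
  if (!is.null(rows)) v <- v[rows, , drop = FALSE]
  if (!is.null(cols)) v <- v[, cols, drop = FALSE]
  feature_matrix(v, x$column_kind[colnames(v)])
}

#' Write a feature matrix to CSV
#'
#' Row identifiers are written as the first column (\code{compound_id}).
#' A sidecar JSON manifest with the per-column kinds can be written next to
#' it by the pipeline.
#'
#' @param x A \code{feature_matrix}.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_feature_matrix <- function(x, path) {
  stopifnot(inherits(x, "feature_matrix"))
  df <- data.frame(compound_id = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a feature matrix from CSV
#'
#' Expects the layout written by \code{\link{write_feature_matrix}} or any
#' CSV whose first column holds compound identifiers and whose remaining
#' columns are numeric features.
#'
#' @param path CSV path.
#' @param column_kind Column kinds; binary columns are tagged
#'   \code{"fingerprint"} automatically when \code{"auto"}.
#' @return A \code{feature_matrix}.
#' @export
read_feature_matrix <- function(path, column_kind = "auto") {
  if (!file.exists(path)) io_error(paste0("cannot read feature matrix: ", path))
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  v <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(v) <- "double"
  rownames(v) <- ids
  if (identical(column_kind, "auto")) {
    column_kind <- ifelse(
      apply(v, 2L, function(col) all(col %in% c(0, 1))),
      "fingerprint", "descriptor")
  }
  feature_matrix(v, column_kind)
}
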