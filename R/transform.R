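#' Scale raw bioactivity values to the unit interval
#'
#' Potency-style activities (Ki, Kd, IC50, EC50, AC50) reported in nM are
#' mapped onto \[0, 1\] with a piecewise log transform: values of 10,000 nM
#' (10 uM) or weaker score 0, values of 1 nM or stronger score 1, and values
#' in between score \code{(4 - log10(value)) / 4}. The transform is
#' continuous at both cut-offs and monotone non-increasing, so stronger
#' binders always score higher.
#'
#' @param raw_value Numeric vector of positive activity values in nM.
#' @return Numeric vector of scaled activities in \[0, 1\].
#' @examples
#' scale_activity(c(1, 100, 10000))
#' @export
scale_activity <- function(raw_value) {
  if (length(raw_value) == 0L) domain_error("no activity values supplied")
  if (!is.numeric(raw_value) || anyNA(raw_value) || any(!is.finite(raw_value)))
    domain_error("activity values must be finite numbers")
  if (any(raw_value <= 0))
    domain_error("activity values must be positive (concentration in nM)")
  out <- (4 - log10(raw_value)) / 4
  out[raw_value >= 10000] <- 0
  out[raw_value <= 1] <- 1
  out
}

#' Fit per-column min-max scaling parameters
#'
#' Records each feature's minimum and maximum over the training rows only,
#' so that external sets can be scaled with the training geometry and never
#' leak into it.
#'
#' @param train_matrix A \code{feature_matrix} or numeric matrix of training
#'   rows. Constant columns are an error: they must have been removed at
#'   feature-block merge time.
#' @return An object of class \code{minmax_params} with numeric vectors
#'   \code{min} and \code{max} named by column.
#' @export
fit_minmax <- function(train_matrix) {
  v <- fm_values(train_matrix)
  mins <- apply(v, 2L, min)
  maxs <- apply(v, 2L, max)
  if (any(maxs <= mins))
    consistency_error(paste0(
      "constant column(s) reached the scaler (should have been removed at merge): ",
      paste(utils::head(colnames(v)[maxs <= mins], 5L), collapse = ", ")))
  structure(list(min = mins, max = maxs), class = "minmax_params")
}

#' Apply fitted min-max scaling
#'
#' Affine per-column transform \code{(x - min) / (max - min)} using
#' parameters fitted on the training set. Training rows land exactly in
#' \[0, 1\]; rows of an external set may fall outside and are deliberately
#' not clipped — out-of-range values are legitimate applicability-domain
#' signal.
#'
#' @param matrix A \code{feature_matrix} or numeric matrix whose columns
#'   match \code{params}.
#' @param params A \code{minmax_params} object from \code{\link{fit_minmax}}.
#' @return Scaled object of the same class as the input.
#' @export
apply_minmax <- function(matrix, params) {
  stopifnot(inherits(params, "minmax_params"))
  v <- fm_values(matrix)
  if (!identical(colnames(v), names(params$min)))
    alignment_error("matrix columns do not match fitted scaler columns")
  scaled <- sweep(sweep(v, 2L, params$min, "-"), 2L,
                  params$max - params$min, "/")
  if (inherits(matrix, "feature_matrix"))
    structure(list(values = scaled, column_kind = matrix$column_kind),
              class = "feature_matrix")
  else scaled
}

#' Randomly partition compounds into training and independent validation sets
#'
#' Draws a uniform random split without replacement, reproducible from the
#' seed. The Independent Validation Set (IVS) is held out of every
#' downstream feature-selection and training step.
#'
#' @param ids Character vector of compound identifiers (length >= 4).
#' @param train_fraction Fraction assigned to training, default 0.75.
#' @param seed Integer seed.
#' @return A list of class \code{data_split} with \code{train_ids},
#'   \code{ivs_ids}, \code{seed}, \code{train_fraction}.
#' @export
partition_data <- function(ids, train_fraction = 0.75, seed = 1L) {
  ids <- as.character(ids)
  n <- length(ids)
  if (n < 4L) too_small_error("at least 4 compounds are required to partition")
  if (!(train_fraction > 0 && train_fraction < 1))
    config_error("train_fraction must lie strictly between 0 and 1")
  n_train <- min(max(round(train_fraction * n), 1L), n - 1L)
  train <- with_seed(seed, sort(sample.int(n, n_train)))
  structure(list(train_ids = ids[train], ivs_ids = ids[-train],
                 seed = as.integer(seed), train_fraction = train_fraction),
            class = "data_split")
}

#' @export
print.data_split <- function(x, ...) {
  cat(sprintf("data_split: %d training / %d IVS (fraction %.2f, seed %d)\n",
              length(x$train_ids), length(x$ivs_ids), x$train_fraction, x$seed))
  invisible(x)
}
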