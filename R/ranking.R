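#' Permutation importance from a single random-forest fit
#'
#' Fits one regression forest and reports, per feature, the raw permutation
#' importance — the mean over trees of the increase in out-of-bag MSE when
#' that feature is randomly permuted — together with its standard error
#' (per-tree standard deviation divided by \code{sqrt(ntree)}). The scaled
#' importance (z-score) is the raw importance divided by this standard
#' error.
#'
#' @param X_train A \code{feature_matrix} or numeric matrix (n >= 10 rows).
#' @param y_train Numeric activity vector.
#' @param ntree Number of trees, >= 50 (default 500).
#' @param mtry Features tried per split; defaults to \code{floor(p/3)}
#'   (regression convention).
#' @param seed Integer seed; the fit is reproducible from it.
#' @return A data.frame with columns \code{feature},
#'   \code{raw_importance}, \code{se}.
#' @export
rf_importance_run <- function(X_train, y_train, ntree = 500L, mtry = NULL,
                              seed = 1L) {
  X <- fm_values(X_train)
  if (nrow(X) < 10L) too_small_error("need at least 10 rows for importance estimation")
  if (ntree < 50L) config_error("ntree must be at least 50")
  if (length(y_train) != nrow(X))
    alignment_error("y_train length does not match rows of X_train")
  # canonical column order: the forest's variable sampling consumes the RNG
  # by column index, so importances must not depend on input column order
  X <- X[, order(colnames(X)), drop = FALSE]
  rf <- with_seed(seed, randomForest::randomForest(
    x = X, y = as.numeric(y_train), ntree = ntree,
    mtry = mtry %||% max(1L, floor(ncol(X) / 3)),
    importance = TRUE))
  raw <- randomForest::importance(rf, type = 1, scale = FALSE)[, 1L]
  data.frame(feature = colnames(X),
             raw_importance = unname(raw),
             se = unname(rf$importanceSD),
             stringsAsFactors = FALSE)
}

#' Aggregate per-run importances into a ranking table
#'
#' The unscaled score of a feature is the arithmetic mean of its raw
#' permutation importances over runs; the scaled score is the mean of the
#' per-run z-scores (raw importance / standard error, with z = 0 for runs
#' whose standard error is zero).
#'
#' @param runs List of data.frames from \code{\link{rf_importance_run}}
#'   over identical feature sets.
#' @param method Active ranking method, \code{"scaled"} or
#'   \code{"unscaled"}.
#' @return An object of class \code{importance_table}: data.frame with
#'   columns \code{feature}, \code{mean_importance}, \code{z_score}, plus
#'   attributes \code{method} and \code{nfold}.
#' @export
aggregate_importance <- function(runs, method = c("scaled", "unscaled")) {
  method <- match.arg(method)
  if (length(runs) < 1L) config_error("need at least one importance run")
  feats <- sort(runs[[1L]]$feature)
  for (r in runs)
    if (!identical(sort(r$feature), feats))
      alignment_error("importance runs cover different feature sets")
  raw <- vapply(runs, function(r) r$raw_importance[match(feats, r$feature)],
                numeric(length(feats)))
  raw <- matrix(raw, nrow = length(feats))
  zs <- vapply(runs, function(r) {
    m <- match(feats, r$feature)
    z <- r$raw_importance[m] / r$se[m]
    z[r$se[m] == 0] <- 0
    z
  }, numeric(length(feats)))
  zs <- matrix(zs, nrow = length(feats))
  out <- data.frame(feature = feats,
                    mean_importance = rowMeans(raw),
                    z_score = rowMeans(zs),
                    stringsAsFactors = FALSE)
  structure(out, class = c("importance_table", "data.frame"),
            method = method, nfold = length(runs))
}

#' Rank features by importance
#'
#' Orders all features descending by the table's active score (ties broken
#' by ascending feature name). No feature is eliminated: ranking only
#' reorders the table for the stepwise wrapper.
#'
#' @param table An \code{importance_table}.
#' @return Character vector of feature names, most important first.
#' @export
rank_features <- function(table) {
  stopifnot(inherits(table, "importance_table"))
  score <- switch(attr(table, "method"),
                  scaled = table$z_score,
                  unscaled = table$mean_importance)
  table$feature[order(-score, table$feature)]
}

#' Cross-validated importance ranking under both scores
#'
#' Repeats the forest fit over the training portions of an nfold split of
#' the training set (run t uses seed \code{seed + t}) and aggregates the
#' recorded importances under both the scaled (z-score) and unscaled (raw
#' mean) methods.
#'
#' @inheritParams rf_importance_run
#' @param nfold Number of cross-validation folds / repeated fits.
#' @return A list with \code{runs} and one \code{importance_table} per
#'   method (\code{scaled}, \code{unscaled}).
#' @export
rank_features_cv <- function(X_train, y_train, nfold = 10L, ntree = 500L,
                             mtry = NULL, seed = 1L) {
  X <- fm_values(X_train)
  n <- nrow(X)
  if (nfold < 2L) config_error("nfold must be at least 2")
  if (n < nfold) too_small_error("fewer rows than folds")
  fold_of <- with_seed(seed, sample(rep_len(seq_len(nfold), n)))
  runs <- lapply(seq_len(nfold), function(t) {
    keep <- fold_of != t
    rf_importance_run(X[keep, , drop = FALSE], y_train[keep],
                      ntree = ntree, mtry = mtry, seed = seed + t)
  })
  list(runs = runs,
       scaled = aggregate_importance(runs, "scaled"),
       unscaled = aggregate_importance(runs, "unscaled"))
}
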