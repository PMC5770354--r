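#' Trace internal-test error while adding ranked features
#'
#' Splits the training partition once into an internal sub-train/test pair
#' (75/25, seeded, held fixed across steps), then fits the learner on
#' cumulative prefixes of the ranked feature list — sizes
#' \code{step_size, 2*step_size, ...} up to all features, with the final
#' full prefix always evaluated — recording internal-test RMSE and PVE at
#' each step. The Independent Validation Set is never touched here.
#'
#' @param X_train Scaled \code{feature_matrix} or matrix (training
#'   partition only).
#' @param y_train Scaled activities named or ordered as the rows.
#' @param ranked Character vector of feature names, most important first.
#' @param learner \code{"svm"} (default, RBF kernel) or \code{"rf"}.
#' @param step_size Features added per step (default 1).
#' @param seed Seed for the internal split (and the forest, if used).
#' @param internal_fraction Internal sub-train fraction, default 0.75.
#' @param ... Learner hyperparameters (\code{cost}, \code{epsilon},
#'   \code{gamma}, \code{ntree}). The SVM kernel width defaults to
#'   1 / (current feature count).
#' @return An object of class \code{stepwise_trace}: data.frame with
#'   columns \code{feature_count}, \code{rmse}, \code{pve}; attributes
#'   carry the learner, seed, internal split and ranking used.
#' @export
stepwise_trace <- function(X_train, y_train, ranked, learner = c("svm", "rf"),
                           step_size = 1L, seed = 1L,
                           internal_fraction = 0.75, ...) {
  learner <- match.arg(learner)
  X <- fm_values(X_train)
  if (length(ranked) == 0L) config_error("ranked feature list is empty")
  if (step_size < 1L) config_error("step_size must be at least 1")
  if (!all(ranked %in% colnames(X)))
    alignment_error("ranked features missing from the matrix")

  split <- partition_data(rownames(X), internal_fraction, seed)
  if (length(split$train_ids) < 4L || length(split$ivs_ids) < 4L)
    too_small_error("internal split leaves fewer than 4 rows on one side")
  y <- if (!is.null(names(y_train))) y_train[rownames(X)] else y_train
  sub <- match(split$train_ids, rownames(X))
  tst <- match(split$ivs_ids, rownames(X))

  counts <- seq.int(step_size, length(ranked), by = step_size)
  if (counts[length(counts)] != length(ranked))
    counts <- c(counts, length(ranked))

  steps <- lapply(counts, function(m) {
    feats <- ranked[seq_len(m)]
    model <- fit_learner(X[sub, feats, drop = FALSE], y[sub],
                         learner = learner, seed = seed, ...)
    pred <- predict_learner(model, X[tst, feats, drop = FALSE])
    data.frame(feature_count = m,
               rmse = compute_rmse(y[tst], pred),
               pve = compute_pve(y[tst], pred))
  })
  out <- do.call(rbind, steps)
  structure(out, class = c("stepwise_trace", "data.frame"),
            learner = learner, seed = as.integer(seed),
            internal_fraction = internal_fraction,
            internal_split = split, ranked = ranked)
}

#' Select the minimal feature subset from a stepwise trace
#'
#' With tolerance 0 picks the step of minimum internal-test RMSE (ties go
#' to the smaller feature count). With tolerance \code{tau > 0} picks the
#' smallest feature count whose RMSE is within \code{tau} of the minimum —
#' an opt-in parsimony relaxation.
#'
#' @param trace A \code{stepwise_trace}.
#' @param ranked Ranked feature list the trace was computed over; defaults
#'   to the one stored in the trace.
#' @param tolerance Non-negative RMSE tolerance, default 0.
#' @return An object of class \code{selected_features}: \code{features}
#'   (the selected ranked prefix), \code{size}, \code{rmse}, \code{pve}.
#' @export
select_features <- function(trace, ranked = NULL, tolerance = 0) {
  stopifnot(inherits(trace, "stepwise_trace"))
  if (tolerance < 0) config_error("tolerance must be non-negative")
  ranked <- ranked %||% attr(trace, "ranked")
  best_rmse <- min(trace$rmse)
  eligible <- which(trace$rmse <= best_rmse + tolerance)
  pick <- eligible[which.min(trace$feature_count[eligible])]
  size <- trace$feature_count[pick]
  structure(list(features = ranked[seq_len(size)], size = size,
                 rmse = trace$rmse[pick], pve = trace$pve[pick],
                 tolerance = tolerance),
            class = "selected_features")
}

#' @export
print.selected_features <- function(x, ...) {
  cat(sprintf("selected %d features (internal-test RMSE %.4f, PVE %.4f)\n",
              x$size, x$rmse, x$pve))
  invisible(x)
}

#' Plot a stepwise RMSE trace
#'
#' @param x A \code{stepwise_trace}.
#' @param ... Passed to \code{plot}.
#' @export
plot.stepwise_trace <- function(x, ...) {
  graphics::plot(x$feature_count, x$rmse, type = "b", pch = 16, cex = 0.6,
                 xlab = "number of ranked features",
                 ylab = "internal-test RMSE", ...)
  best <- which.min(x$rmse)
  graphics::abline(v = x$feature_count[best], lty = 2, col = "grey40")
  invisible(x)
}
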