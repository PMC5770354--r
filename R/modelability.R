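#' Leave-one-out k-nearest-neighbour predictions
#'
#' For each compound, predicts its activity as the unweighted mean activity
#' of its k nearest neighbours by Euclidean distance over all (scaled)
#' feature columns, with the compound itself excluded. Distance ties are
#' broken in favour of the lower row index, making the result deterministic.
#'
#' @param X A \code{feature_matrix} or numeric matrix, scaled to \[0, 1\].
#' @param y Numeric activity vector aligned with the rows of \code{X}.
#' @param k Number of neighbours; must be smaller than the number of rows.
#' @return Numeric vector of LOO predictions.
#' @export
knn_loo_predictions <- function(X, y, k) {
  v <- fm_values(X)
  n <- nrow(v)
  if (length(y) != n) alignment_error("y length does not match rows of X")
  if (n <= k) too_small_error(sprintf("need more than k = %d rows (have %d)", k, n))
  d <- as.matrix(stats::dist(v))
  vapply(seq_len(n), function(i) {
    others <- setdiff(seq_len(n), i)
    # order() is stable: equal distances resolve to the lower row index
    nn <- others[order(d[i, others])][seq_len(k)]
    mean(y[nn])
  }, numeric(1))
}

#' Regression modelability score (coefficient of determination of LOO kNN)
#'
#' \code{1 - SSE/SST} between observed activities and their leave-one-out
#' kNN predictions. Can be negative when neighbours predict worse than the
#' mean — the signature of activity cliffs.
#'
#' @param y Observed activities.
#' @param y_hat LOO kNN predictions.
#' @return Scalar score, at most 1.
#' @export
modi_ssr2 <- function(y, y_hat) {
  if (length(y) != length(y_hat)) alignment_error("y and y_hat differ in length")
  if (length(y) < 2L) too_small_error("need at least 2 observations")
  sst <- sum((y - mean(y))^2)
  if (sst == 0)
    domain_error("constant activities: modelability is undefined")
  1 - sum((y - y_hat)^2) / sst
}

#' Estimate dataset modelability (MODI)
#'
#' Runs leave-one-out kNN on the scaled training set for each requested k
#' and scores the agreement as a coefficient of determination. A dataset
#' whose score at the gating k exceeds the threshold is considered
#' modelable; low scores flag datasets (e.g. with activity cliffs) where
#' QSAR modeling is unlikely to succeed without further curation.
#'
#' @param X Scaled \code{feature_matrix} or matrix (training partition).
#' @param y Scaled activities in \[0, 1\].
#' @param k Neighbour counts to evaluate (default both 3 and 5).
#' @param gate_k The k whose score is used for the gate decision (default 5).
#' @param threshold Gate threshold, default 0.45 (strict inequality).
#' @return An object of class \code{modi_result}: data.frame of scores per
#'   k plus \code{gate_threshold}, \code{gate_k}, \code{score} (at gate_k)
#'   and \code{passed}.
#' @export
modi <- function(X, y, k = c(3L, 5L), gate_k = 5L, threshold = 0.45) {
  scores <- vapply(k, function(kk)
    modi_ssr2(y, knn_loo_predictions(X, y, kk)), numeric(1))
  if (!gate_k %in% k) config_error("gate_k must be one of the evaluated k")
  gate_score <- scores[match(gate_k, k)]
  structure(list(
    scores = data.frame(k = as.integer(k), score = scores),
    gate_k = as.integer(gate_k), score = gate_score,
    gate_threshold = threshold, passed = gate_score > threshold
  ), class = "modi_result")
}

#' @export
print.modi_result <- function(x, ...) {
  for (i in seq_len(nrow(x$scores)))
    cat(sprintf("MODI(k=%d) = %.4f\n", x$scores$k[i], x$scores$score[i]))
  cat(sprintf("gate (k=%d): score %.4f %s threshold %.2f -> %s\n",
              x$gate_k, x$score, if (x$passed) ">" else "<=",
              x$gate_threshold, if (x$passed) "PASSED" else "FAILED"))
  invisible(x)
}

#' Gate the pipeline on modelability
#'
#' In \code{"halt"} mode a failing score aborts the run with curation
#' advice; in \code{"warn"} mode the pipeline proceeds with a logged
#' warning.
#'
#' @param result A \code{modi_result}.
#' @param mode \code{"warn"} or \code{"halt"}.
#' @return \code{result$passed}, invisibly.
#' @export
modelability_gate <- function(result, mode = c("warn", "halt")) {
  mode <- match.arg(mode)
  stopifnot(inherits(result, "modi_result"))
  if (!result$passed) {
    msg <- sprintf(paste0(
      "dataset modelability MODI(k=%d) = %.3f does not exceed %.2f; ",
      "the dataset likely contains activity cliffs or inconsistent ",
      "measurements - additional curation is advised before modeling"),
      result$gate_k, result$score, result$gate_threshold)
    if (mode == "halt")
      abort_aq(msg, "autoqsar_modi_gate_error")
    warning(msg, call. = FALSE)
  }
  invisible(result$passed)
}
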