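#' Proportion of variance explained
#'
#' \code{PVE = 1 - sum((y - y_hat)^2) / sum((y - mean(y))^2)}. Negative for
#' models predicting worse than the observed mean.
#'
#' @param y Observed values (non-constant, length >= 2).
#' @param y_hat Predicted values of equal length.
#' @return Scalar PVE, at most 1.
#' @export
compute_pve <- function(y, y_hat) {
  if (length(y) != length(y_hat)) alignment_error("y and y_hat differ in length")
  if (length(y) < 2L) too_small_error("need at least 2 observations for PVE")
  sst <- sum((y - mean(y))^2)
  if (sst == 0) domain_error("constant observed values: PVE undefined")
  1 - sum((y - y_hat)^2) / sst
}

#' Root mean squared error
#'
#' @param y Observed values (length >= 1).
#' @param y_hat Predicted values of equal length.
#' @return Scalar RMSE, non-negative.
#' @export
compute_rmse <- function(y, y_hat) {
  if (length(y) == 0L) domain_error("empty input to RMSE")
  if (length(y) != length(y_hat)) alignment_error("y and y_hat differ in length")
  sqrt(mean((y - y_hat)^2))
}

# Fit the configured learner. gamma defaults to 1/p (libsvm convention);
# features are already [0,1]-scaled so svm's internal scaling is off.
fit_learner <- function(X, y, learner = c("svm", "rf"),
                        cost = 1, epsilon = 0.1, gamma = NULL,
                        ntree = 500L, seed = 1L) {
  learner <- match.arg(learner)
  X <- fm_values(X)
  if (learner == "svm") {
    e1071::svm(x = X, y = y, type = "eps-regression", kernel = "radial",
               cost = cost, epsilon = epsilon,
               gamma = gamma %||% (1 / ncol(X)), scale = FALSE)
  } else {
    with_seed(seed, randomForest::randomForest(
      x = X, y = y, ntree = ntree,
      mtry = max(1L, floor(ncol(X) / 3))))
  }
}

predict_learner <- function(model, X) {
  unname(stats::predict(model, fm_values(X)))
}

#' Fit a model on a feature subset and validate it externally
#'
#' Fits the learner on the full training partition restricted to
#' \code{features}, scores it on the Independent Validation Set (Eq.-style
#' PVE and RMSE), and optionally replays the internal train/test split used
#' during stepwise selection so internal and external scores are directly
#' comparable.
#'
#' @param X_train,y_train Scaled training features and activities.
#' @param X_ivs,y_ivs Scaled IVS features (training-set scaler) and
#'   activities.
#' @param features Character vector of feature names to use; \code{NULL}
#'   means all columns (the "full model").
#' @param learner \code{"svm"} (default) or \code{"rf"}.
#' @param internal_split Optional \code{data_split} over the training
#'   partition; when given, internal-test PVE/RMSE are reported from a fit
#'   on its training side.
#' @param model_label Label recorded in the report row.
#' @param seed Seed for stochastic learners.
#' @param ... Learner hyperparameters passed to the fitting routine
#'   (\code{cost}, \code{epsilon}, \code{gamma}, \code{ntree}).
#' @return A list of class \code{validated_model}: \code{model} (fitted on
#'   the full training partition), \code{features}, \code{report}
#'   (data.frame with one row per evaluation set), \code{predictions_ivs}.
#' @export
fit_and_validate <- function(X_train, y_train, X_ivs, y_ivs,
                             features = NULL, learner = "svm",
                             internal_split = NULL,
                             model_label = "model", seed = 1L, ...) {
  Xt <- fm_values(X_train); Xi <- fm_values(X_ivs)
  if (is.null(features)) features <- colnames(Xt)
  if (length(features) == 0L) config_error("feature subset must not be empty")
  missing_cols <- setdiff(features, colnames(Xt))
  if (length(missing_cols) > 0L)
    alignment_error(paste0("feature(s) not in matrix: ",
                           paste(utils::head(missing_cols, 5L), collapse = ", ")))
  Xt <- Xt[, features, drop = FALSE]
  Xi <- Xi[, features, drop = FALSE]

  model <- fit_learner(Xt, y_train, learner = learner, seed = seed, ...)
  pred_ivs <- predict_learner(model, Xi)
  report <- data.frame(
    model = model_label, set = "ivs", n = length(y_ivs),
    n_features = length(features),
    pve = compute_pve(y_ivs, pred_ivs),
    rmse = compute_rmse(y_ivs, pred_ivs),
    stringsAsFactors = FALSE)

  if (!is.null(internal_split)) {
    sub <- internal_split$train_ids; tst <- internal_split$ivs_ids
    m_int <- fit_learner(Xt[sub, , drop = FALSE], y_train[match(sub, rownames(Xt))],
                         learner = learner, seed = seed, ...)
    pred_int <- predict_learner(m_int, Xt[tst, , drop = FALSE])
    y_int <- y_train[match(tst, rownames(Xt))]
    report <- rbind(data.frame(
      model = model_label, set = "internal_test", n = length(y_int),
      n_features = length(features),
      pve = compute_pve(y_int, pred_int),
      rmse = compute_rmse(y_int, pred_int),
      stringsAsFactors = FALSE), report)
  }

  structure(list(model = model, learner = learner, features = features,
                 report = report, predictions_ivs = pred_ivs,
                 seed = as.integer(seed)),
            class = "validated_model")
}

# Euclidean distances from each row of A to each row of B.
cross_dist <- function(A, B) {
  a2 <- rowSums(A^2); b2 <- rowSums(B^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(A, B)
  sqrt(pmax(d2, 0))
}

#' Applicability-domain check by nearest-neighbour Euclidean distance
#'
#' The domain threshold is \code{mean + Z * sd} of each training compound's
#' distance to its nearest training neighbour (self excluded), computed in
#' the scaled feature space of the model being assessed. An external
#' compound is flagged outside the domain when its distance to the nearest
#' training compound strictly exceeds the threshold. Flagged compounds are
#' reported, never removed: the decision is left to the user.
#'
#' @param X_train_scaled,X_ivs_scaled Scaled feature matrices sharing
#'   columns.
#' @param Z Multiplier on the standard deviation, default 0.5.
#' @return An object of class \code{ad_report}: \code{threshold}, \code{Z},
#'   and a data.frame \code{compounds} with per-IVS-compound nearest
#'   training distance and in/out flag.
#' @export
applicability_domain <- function(X_train_scaled, X_ivs_scaled, Z = 0.5) {
  A <- fm_values(X_train_scaled); B <- fm_values(X_ivs_scaled)
  if (!identical(colnames(A), colnames(B)))
    alignment_error("training and IVS matrices must share columns")
  if (nrow(A) < 2L) too_small_error("need at least 2 training compounds for AD")
  dtt <- cross_dist(A, A)
  diag(dtt) <- Inf
  nn_train <- apply(dtt, 1L, min)
  threshold <- mean(nn_train) + Z * stats::sd(nn_train)
  nn_ivs <- apply(cross_dist(B, A), 1L, min)
  structure(list(
    threshold = threshold, Z = Z,
    train_nn_mean = mean(nn_train), train_nn_sd = stats::sd(nn_train),
    compounds = data.frame(
      compound_id = rownames(B) %||% as.character(seq_len(nrow(B))),
      nn_distance = unname(nn_ivs),
      in_domain = unname(nn_ivs <= threshold),
      stringsAsFactors = FALSE)
  ), class = "ad_report")
}

#' @export
print.ad_report <- function(x, ...) {
  n_out <- sum(!x$compounds$in_domain)
  cat(sprintf("applicability domain: threshold %.4f (mean %.4f + %.2f * sd %.4f)\n",
              x$threshold, x$train_nn_mean, x$Z, x$train_nn_sd))
  cat(sprintf("%d of %d external compounds outside the domain\n",
              n_out, nrow(x$compounds)))
  invisible(x)
}
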