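test_that("permutation importance is reproducible and zero for constants", {
  d <- make_regression_dataset(n = 60, p = 15, n_informative = 4, seed = 3)
  X <- as.matrix(d$features)
  X <- cbind(X, flat_col = 0.5)
  r1 <- rf_importance_run(X, unname(d$activity), ntree = 100L, seed = 5L)
  r2 <- rf_importance_run(X, unname(d$activity), ntree = 100L, seed = 5L)
  expect_identical(r1, r2)
  expect_equal(r1$raw_importance[r1$feature == "flat_col"], 0)
  expect_equal(r1$se[r1$feature == "flat_col"], 0)
  expect_error(rf_importance_run(X[1:5, ], d$activity[1:5], ntree = 100L),
               class = "autoqsar_too_small_error")
  expect_error(rf_importance_run(X, unname(d$activity), ntree = 10L),
               class = "autoqsar_config_error")
})

test_that("aggregation averages runs and guards zero standard errors", {
  run1 <- data.frame(feature = c("a", "b"), raw_importance = c(0.2, 0.1),
                     se = c(0.05, 0.02))
  run2 <- data.frame(feature = c("b", "a"), raw_importance = c(0.3, 0.4),
                     se = c(0.06, 0))
  one <- aggregate_importance(list(run1), "unscaled")
  expect_equal(one$mean_importance[one$feature == "a"], 0.2)
  both <- aggregate_importance(list(run1, run2), "unscaled")
  expect_equal(both$mean_importance[both$feature == "a"], 0.3)
  expect_equal(both$mean_importance[both$feature == "b"], 0.2)
  # zero se contributes z = 0 instead of dividing by zero
  expect_equal(both$z_score[both$feature == "a"], (0.2 / 0.05 + 0) / 2)
  expect_error(aggregate_importance(list(run1, run1[1, ])),
               class = "autoqsar_alignment_error")
  # run order does not matter
  expect_equal(aggregate_importance(list(run2, run1), "unscaled"),
               both, ignore_attr = TRUE)
})

test_that("ranking is total, descending, and tie-broken by feature name", {
  tab <- structure(
    data.frame(feature = c("a", "b", "c"),
               mean_importance = c(0.3, 0.1, 0.3),
               z_score = c(1, 2, 3)),
    class = c("importance_table", "data.frame"),
    method = "unscaled", nfold = 1L)
  expect_identical(rank_features(tab), c("a", "c", "b"))
  attr(tab, "method") <- "scaled"
  expect_identical(rank_features(tab), c("c", "b", "a"))
  tab$mean_importance <- rep(0.5, 3)
  attr(tab, "method") <- "unscaled"
  expect_identical(rank_features(tab), c("a", "b", "c"))
})

test_that("rankings are invariant to input column order", {
  d <- make_regression_dataset(n = 80, p = 20, n_informative = 5, seed = 12)
  X <- as.matrix(d$features)
  rk1 <- rank_features_cv(X, unname(d$activity), nfold = 3L, ntree = 100L,
                          seed = 2L)
  perm <- sample(ncol(X))
  rk2 <- rank_features_cv(X[, perm], unname(d$activity), nfold = 3L,
                          ntree = 100L, seed = 2L)
  expect_identical(rank_features(rk1$unscaled), rank_features(rk2$unscaled))
  expect_identical(rank_features(rk1$scaled), rank_features(rk2$scaled))
})

test_that("informative features dominate the ranking on easy synthetic data", {
  d <- make_regression_dataset(n = 150, p = 50, n_informative = 5,
                               noise_sd = 0.05, seed = 21)
  Xs <- apply_minmax(d$features, fit_minmax(d$features))
  run <- rf_importance_run(Xs, unname(d$activity), ntree = 500L, seed = 1L)
  tab <- aggregate_importance(list(run), "unscaled")
  top15 <- rank_features(tab)[1:15]
  expect_true(all(d$informative %in% top15))
})
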