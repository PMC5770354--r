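test_that("the regression generator honours its spec and is reproducible", {
  d <- make_regression_dataset(n = 300, p = 200, n_informative = 10,
                               noise_sd = 0.05, seed = 1)
  expect_equal(dim(d$features), c(300L, 200L))
  expect_length(d$informative, 10L)
  expect_true(all(d$informative %in% colnames(as.matrix(d$features))))
  expect_true(all(d$activity >= 0 & d$activity <= 1))
  expect_equal(sum(d$features$column_kind == "fingerprint"), 100L)
  fp_cols <- names(d$features$column_kind)[d$features$column_kind == "fingerprint"]
  expect_true(all(as.matrix(d$features)[, fp_cols] %in% c(0, 1)))
  d2 <- make_regression_dataset(n = 300, p = 200, n_informative = 10,
                                noise_sd = 0.05, seed = 1)
  expect_identical(d, d2)
  expect_false(identical(
    d$activity, make_regression_dataset(n = 300, p = 200, seed = 2)$activity))
  expect_error(make_regression_dataset(p = 5, n_informative = 10),
               class = "autoqsar_config_error")
})

test_that("a noise-free linear response is exactly recoverable", {
  d <- make_regression_dataset(n = 100, p = 30, n_informative = 5,
                               noise_sd = 0, response_form = "linear",
                               seed = 8)
  fit <- stats::lm(y ~ ., data = data.frame(
    y = unname(d$activity),
    as.matrix(d$features)[, d$informative]))
  expect_lt(max(abs(stats::residuals(fit))), 1e-10)
})

test_that("the cliff generator produces unmodelable neighbourhoods", {
  cl <- make_activity_cliff_dataset(n = 100, p = 200, cliff_fraction = 1,
                                    seed = 1)
  expect_equal(dim(cl$features), c(100L, 200L))
  m <- modi(cl$features, cl$activity, k = 3L, gate_k = 3L)
  expect_lt(m$score, 0.2)
  # LOO predictions for cliff pairs sit on the wrong side: each compound's
  # nearest neighbour carries the opposite activity
  pred <- knn_loo_predictions(cl$features, unname(cl$activity), 1L)
  y <- unname(cl$activity)
  expect_gt(mean(abs(pred - y)), 0.8)
  # cliff_fraction = 0 delegates to the smooth generator
  base <- make_regression_dataset(n = 50, p = 20, n_informative = 10,
                                  noise_sd = 0.05, seed = 4)
  deleg <- make_activity_cliff_dataset(n = 50, p = 20, cliff_fraction = 0,
                                       n_informative = 10, seed = 4)
  expect_identical(deleg$activity, base$activity)
})

test_that("the embedded SMILES fixture plants every curation branch", {
  fx <- make_smiles_fixture()
  expect_gte(nrow(fx), 40L)
  expect_gte(sum(grepl(".", fx$smiles, fixed = TRUE)), 1L)  # salt form
  expect_equal(sum(fx$smiles == "notasmiles"), 1L)          # invalid
  expect_equal(sum(is.na(fx$activity_value)), 1L)           # missing value
  expect_gte(sum(fx$activity_type != "Ki"), 1L)             # other type
  expect_true(anyDuplicated(fx$compound_id) == 0L)
})
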