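test_that("PVE and RMSE match brute-force reimplementations on random vectors", {
  set.seed(123)
  for (trial in 1:100) {
    n <- sample(2:1000, 1)
    y <- rnorm(n)
    y_hat <- y + rnorm(n, sd = runif(1, 0, 2))
    expect_equal(compute_pve(y, y_hat), oracle_pve(y, y_hat),
                 tolerance = 1e-10)
    expect_equal(compute_rmse(y, y_hat), oracle_rmse(y, y_hat),
                 tolerance = 1e-10)
  }
})

test_that("PVE and RMSE handle their canonical examples and edge cases", {
  y <- c(0, 1, 2)
  expect_equal(compute_pve(y, y), 1)
  expect_equal(compute_pve(y, rep(mean(y), 3)), 0)
  expect_equal(compute_pve(y, c(0, 1, 1)), 0.5)
  expect_equal(compute_rmse(y, y), 0)
  expect_equal(compute_rmse(c(0, 0), c(1, 1)), 1)
  expect_equal(compute_rmse(c(0, 2), c(1, 1)), 1)
  expect_error(compute_pve(rep(3, 4), rep(3, 4)),
               class = "autoqsar_domain_error")
  expect_error(compute_rmse(numeric(0), numeric(0)),
               class = "autoqsar_domain_error")
  # PVE is invariant under a joint affine transform of y and y_hat
  set.seed(5)
  y <- runif(50); y_hat <- y + rnorm(50, sd = 0.3)
  expect_equal(compute_pve(3 * y - 7, 3 * y_hat - 7), compute_pve(y, y_hat))
})

test_that("fitting on all features reproduces the full model", {
  d <- make_regression_dataset(n = 80, p = 20, n_informative = 5, seed = 4)
  sp <- partition_data(names(d$activity), 0.75, 2L)
  Xtr <- as.matrix(d$features)[sp$train_ids, ]
  Xiv <- as.matrix(d$features)[sp$ivs_ids, ]
  full <- fit_and_validate(Xtr, d$activity[sp$train_ids], Xiv,
                           d$activity[sp$ivs_ids], NULL,
                           model_label = "full")
  again <- fit_and_validate(Xtr, d$activity[sp$train_ids], Xiv,
                            d$activity[sp$ivs_ids], colnames(Xtr),
                            model_label = "all")
  expect_equal(full$report$pve, again$report$pve)
  expect_equal(full$predictions_ivs, again$predictions_ivs)
  expect_error(fit_and_validate(Xtr, d$activity[sp$train_ids], Xiv,
                                d$activity[sp$ivs_ids], character(0)),
               class = "autoqsar_config_error")
  expect_error(fit_and_validate(Xtr, d$activity[sp$train_ids], Xiv,
                                d$activity[sp$ivs_ids], c("nope")),
               class = "autoqsar_alignment_error")
})

test_that("model bundles round-trip predictions bit-exactly", {
  d <- make_regression_dataset(n = 60, p = 15, n_informative = 4, seed = 6)
  sp <- partition_data(names(d$activity), 0.75, 3L)
  Xtr <- as.matrix(d$features)[sp$train_ids, ]
  Xiv <- as.matrix(d$features)[sp$ivs_ids, ]
  scaler <- fit_minmax(Xtr)
  Xtr_s <- apply_minmax(Xtr, scaler)
  Xiv_s <- apply_minmax(Xiv, scaler)
  vm <- fit_and_validate(Xtr_s, d$activity[sp$train_ids], Xiv_s,
                         d$activity[sp$ivs_ids],
                         features = colnames(Xtr)[1:8])
  dir <- tempfile("bundle")
  save_model_bundle(vm, dir, scaler, Xtr_s)
  preds <- predict_external(dir, data.frame(compound_id = sp$ivs_ids,
                                            Xiv, check.names = FALSE))
  expect_equal(preds$prediction, vm$predictions_ivs, tolerance = 1e-12)
  # a second load gives identical output
  preds2 <- predict_external(load_model_bundle(dir),
                             data.frame(compound_id = sp$ivs_ids, Xiv,
                                        check.names = FALSE))
  expect_identical(preds, preds2)
  # training rows are always inside the applicability domain
  tr_preds <- predict_external(dir, data.frame(compound_id = sp$train_ids,
                                               Xtr, check.names = FALSE))
  expect_true(all(tr_preds$in_domain))
  # a feature row missing one model column is an alignment error naming it
  broken <- data.frame(compound_id = sp$ivs_ids,
                       Xiv[, -1, drop = FALSE], check.names = FALSE)
  expect_error(predict_external(dir, broken), colnames(Xtr)[1],
               class = "autoqsar_alignment_error")
})

test_that("applicability domain flags exactly the far-out compounds", {
  # unit square of training points: every nearest-neighbour distance is 1,
  # so the spread is 0 and the threshold equals 1 for any Z
  tr <- matrix(c(0, 0, 0, 1, 1, 0, 1, 1), 4, 2, byrow = TRUE,
               dimnames = list(paste0("t", 1:4), c("x", "y")))
  ivs <- matrix(c(0, 0, 5, 0, 0, 2), 3, 2, byrow = TRUE,
                dimnames = list(paste0("v", 1:3), c("x", "y")))
  ad <- applicability_domain(tr, ivs, Z = 0.5)
  expect_equal(ad$threshold, 1)
  expect_equal(ad$compounds$nn_distance, c(0, 4, 1))
  # distance 4 exceeds the threshold; distance exactly 1 sits on the
  # boundary and stays inside (only a strict exceedance flags out)
  expect_equal(ad$compounds$in_domain, c(TRUE, FALSE, TRUE))
  # boundary rule: distance exactly at the threshold stays inside
  ivs_b <- matrix(c(0, -1), 1, 2, dimnames = list("b", c("x", "y")))
  expect_true(applicability_domain(tr, ivs_b, Z = 0.5)$compounds$in_domain)
  # flags are invariant to row order on both sides
  set.seed(8)
  tr2 <- matrix(runif(40), 10, 4,
                dimnames = list(paste0("t", 1:10), paste0("f", 1:4)))
  iv2 <- matrix(runif(24, -1, 2), 6, 4,
                dimnames = list(paste0("v", 1:6), paste0("f", 1:4)))
  a1 <- applicability_domain(tr2, iv2)
  perm_t <- sample(10); perm_v <- sample(6)
  a2 <- applicability_domain(tr2[perm_t, ], iv2[perm_v, ])
  expect_equal(a1$threshold, a2$threshold)
  m <- match(a1$compounds$compound_id, a2$compounds$compound_id)
  expect_equal(a1$compounds$in_domain, a2$compounds$in_domain[m])
  expect_error(applicability_domain(tr[1, , drop = FALSE], ivs),
               class = "autoqsar_too_small_error")
})
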