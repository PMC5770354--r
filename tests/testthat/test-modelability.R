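test_that("LOO kNN predictions match the exhaustive pairwise oracle", {
  for (case in list(c(n = 10, p = 3, seed = 1), c(n = 25, p = 8, seed = 2),
                    c(n = 50, p = 20, seed = 3))) {
    d <- random_dataset(case["n"], case["p"], case["seed"])
    for (k in c(3L, 5L)) {
      expect_equal(knn_loo_predictions(d$X, d$y, k),
                   oracle_knn_loo(d$X, d$y, k), tolerance = 1e-12)
    }
  }
  # and on a structured synthetic dataset
  s <- make_regression_dataset(n = 40, p = 12, n_informative = 4, seed = 9)
  expect_equal(knn_loo_predictions(s$features, unname(s$activity), 5L),
               oracle_knn_loo(as.matrix(s$features), unname(s$activity), 5L),
               tolerance = 1e-12)
})

test_that("kNN edge cases: n=4 means the mean of the rest, ties go low-index", {
  d <- random_dataset(4, 3, 7)
  pred <- knn_loo_predictions(d$X, d$y, 3L)
  for (i in 1:4) expect_equal(pred[i], mean(d$y[-i]))
  # four identical points: every neighbour is at distance 0, tie-broken by
  # taking the lowest row indices
  X <- matrix(1, 4, 2, dimnames = list(paste0("r", 1:4), c("a", "b")))
  y <- c(10, 20, 30, 40)
  pred <- knn_loo_predictions(X, y, 2L)
  expect_equal(pred, c(mean(y[2:3]), mean(y[c(1, 3)]),
                       mean(y[1:2]), mean(y[1:2])))
  expect_error(knn_loo_predictions(X, y, 4L),
               class = "autoqsar_too_small_error")
  # constant activities predict that constant
  expect_equal(knn_loo_predictions(d$X, rep(2, 4), 3L), rep(2, 4))
})

test_that("modelability score is the LOO coefficient of determination", {
  y <- c(0, 1, 2)
  expect_equal(modi_ssr2(y, y), 1)
  expect_equal(modi_ssr2(y, rep(mean(y), 3)), 0)
  expect_equal(modi_ssr2(y, c(0, 1, 1)), 0.5)
  expect_error(modi_ssr2(rep(1, 5), rep(1, 5)),
               class = "autoqsar_domain_error")
  expect_error(modi_ssr2(1:3, 1:2), class = "autoqsar_alignment_error")
})

test_that("modelability agrees with a full brute-force recomputation", {
  for (seed in 1:3) {
    d <- random_dataset(30, 6, seed + 40)
    m <- modi(d$X, d$y)
    for (i in seq_len(nrow(m$scores))) {
      k <- m$scores$k[i]
      expect_equal(m$scores$score[i],
                   oracle_pve(d$y, oracle_knn_loo(d$X, d$y, k)),
                   tolerance = 1e-12)
    }
  }
})

test_that("duplicating every row never decreases the modelability score", {
  for (seed in c(3, 11)) {
    d <- random_dataset(20, 4, seed)
    base <- modi(d$X, d$y, k = 3L, gate_k = 3L)$score
    X2 <- rbind(d$X, d$X)
    rownames(X2) <- paste0("r", seq_len(40))
    doubled <- modi(X2, c(d$y, d$y), k = 3L, gate_k = 3L)$score
    expect_gte(doubled, base)
  }
})

test_that("the gate uses a strict threshold and halt mode aborts", {
  fake <- function(score) structure(
    list(scores = data.frame(k = 5L, score = score), gate_k = 5L,
         score = score, gate_threshold = 0.45, passed = score > 0.45),
    class = "modi_result")
  expect_true(modelability_gate(fake(0.46), "warn"))
  expect_warning(modelability_gate(fake(0.45), "warn"), "modelability")
  expect_false(suppressWarnings(modelability_gate(fake(0.45), "warn")))
  expect_error(modelability_gate(fake(0.30), "halt"),
               class = "autoqsar_modi_gate_error")
})
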