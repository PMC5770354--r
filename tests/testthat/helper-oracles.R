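# Independent brute-force oracles and tiny fixtures, written without
# reference to the package internals they check.

oracle_pve <- function(y, y_hat) {
  sse <- 0; sst <- 0; ybar <- sum(y) / length(y)
  for (i in seq_along(y)) {
    sse <- sse + (y[i] - y_hat[i])^2
    sst <- sst + (y[i] - ybar)^2
  }
  1 - sse / sst
}

oracle_rmse <- function(y, y_hat) {
  s <- 0
  for (i in seq_along(y)) s <- s + (y[i] - y_hat[i])^2
  sqrt(s / length(y))
}

# exhaustive pairwise distances, explicit stable neighbour sort
oracle_knn_loo <- function(X, y, k) {
  n <- nrow(X)
  out <- numeric(n)
  for (i in seq_len(n)) {
    cand <- setdiff(seq_len(n), i)
    d <- numeric(length(cand))
    for (jj in seq_along(cand))
      d[jj] <- sqrt(sum((X[i, ] - X[cand[jj], ])^2))
    nn <- cand[order(d)][seq_len(k)]
    out[i] <- mean(y[nn])
  }
  out
}

random_dataset <- function(n, p, seed) {
  set.seed(seed)
  X <- matrix(runif(n * p), n, p,
              dimnames = list(paste0("r", seq_len(n)),
                              paste0("f", seq_len(p))))
  list(X = X, y = runif(n))
}

# minimal V2000 SDF (ethanol + methane) with activity tags
write_tiny_sdf <- function(path) {
  atom <- function(sym) sprintf(
    "    0.0000    0.0000    0.0000 %s   0  0  0  0  0  0  0  0  0  0  0  0",
    sym)
  lines <- c(
    "ethanol", "  autoqsar", "",
    "  3  2  0  0  0  0  0  0  0  0999 V2000",
    atom("C"), atom("C"), atom("O"),
    "  1  2  1  0", "  2  3  1  0",
    "M  END",
    ">  <activity_type>", "Ki", "",
    ">  <activity_value>", "100", "",
    ">  <year>", "2015", "",
    "$$$$",
    "methane", "  autoqsar", "",
    "  1  0  0  0  0  0  0  0  0  0999 V2000",
    atom("C"),
    "M  END",
    ">  <activity_type>", "Ki", "",
    ">  <activity_value>", "2500", "",
    "$$$$")
  writeLines(lines, path)
  path
}

write_records_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, na = "")
  path
}
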