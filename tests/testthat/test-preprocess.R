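test_that("a zero-distance neighbour donates its value directly (k = 1)", {
  # f2 identical to f1 on all observed samples
  v <- rbind(
    c(1, 2, NA, 4),
    c(1, 2, 99, 4),
    c(7, 5, 3, 1)
  )
  mt <- make_table(v, rep("biological", 4))
  out <- knn_impute(mt, k = 1)
  expect_equal(out$values["F1", "S3"], 99)
  # observed cells never change
  obs <- !is.na(v)
  expect_identical(out$values[obs], v[obs])
})

test_that("imputation without missing values is the identity", {
  v <- matrix(1:12, 3, 4)
  mt <- make_table(v, rep("biological", 4))
  expect_identical(knn_impute(mt, 5)$values, mt$values)
})

test_that("two equidistant neighbours average equally (k = 2)", {
  v <- rbind(
    c(1, 2, NA),
    c(2, 3, 10),
    c(0, 1, 20)
  )
  mt <- make_table(v, rep("biological", 3))
  out <- knn_impute(mt, k = 2)
  expect_equal(out$values["F1", "S3"], 15)
})

test_that("imputed values are positive and complete on simulated data", {
  cfg <- sim_config(n_features = 120, seed = 14)
  sim <- simulate_feature_table(cfg)
  qc <- run_qc_cascade(sim$table)
  out <- knn_impute(qc$table, 5)
  expect_false(anyNA(out$values))
  expect_true(all(out$values > 0))
  obs <- !is.na(qc$table$values)
  expect_identical(out$values[obs], qc$table$values[obs])
})

test_that("a feature with no observed value is rejected", {
  v <- rbind(c(NA, NA, NA), c(1, 2, 3))
  mt <- make_table(v, rep("biological", 3))
  expect_error(knn_impute(mt), "no observed values")
})

test_that("PQN recovers an exact dilution factor", {
  # one QC defines the reference spectrum [10, 20, 30]
  v <- cbind(c(10, 20, 30), c(20, 40, 60))
  mt <- make_table(v, c("qc", "biological"))
  res <- pqn_normalize(mt)
  expect_equal(res$factors$factor, c(1, 2))
  expect_equal(unname(res$table$values[, 2]), c(10, 20, 30))
})

test_that("a sample equal to the reference is unchanged", {
  v <- cbind(c(10, 20, 30), c(10, 20, 30))
  mt <- make_table(v, c("qc", "biological"))
  res <- pqn_normalize(mt)
  expect_equal(res$factors$factor[2], 1)
  expect_equal(res$table$values[, 2], mt$values[, 2])
})

test_that("PQN is idempotent on pure-dilution data", {
  withr::local_seed(15)
  spectrum <- rlnorm(50, 8, 1)
  d <- c(1, 1, 1, runif(6, 0.7, 1.4)) # 3 QCs at unit dilution
  v <- outer(spectrum, d)
  mt <- make_table(v, c(rep("qc", 3), rep("biological", 6)))
  first <- pqn_normalize(mt)
  second <- pqn_normalize(first$table)
  expect_equal(second$factors$factor, rep(1, 9), tolerance = 1e-9)
})

test_that("second-pass PQN factors stay near one on noisy data", {
  cfg <- sim_config(n_features = 400, effects = list(), seed = 16)
  sim <- simulate_feature_table(cfg)
  imp <- knn_impute(run_qc_cascade(sim$table)$table)
  second <- pqn_normalize(pqn_normalize(imp)$table)
  expect_true(all(abs(second$factors$factor - 1) < 0.05))
})

test_that("PQN factors are scale-equivariant", {
  withr::local_seed(17)
  v <- matrix(rlnorm(60, 8, 1), 10, 6)
  mt <- make_table(v, c("qc", "qc", rep("biological", 4)))
  base <- pqn_normalize(mt)
  v2 <- v
  v2[, 4] <- v[, 4] * 3
  mt2 <- make_table(v2, c("qc", "qc", rep("biological", 4)))
  scaled <- pqn_normalize(mt2)
  expect_equal(
    scaled$factors$factor[4], base$factors$factor[4] * 3,
    tolerance = 1e-12
  )
})

test_that("glog reduces to the natural log at lambda zero", {
  v <- matrix(2, 1, 2)
  mt <- make_table(v, c("qc", "biological"))
  out <- glog_transform(mt, lambda = 0)
  expect_equal(out$values[1, 1], log(2))

  big <- make_table(matrix(c(1, 5, 100, 2.5), 2, 2), c("qc", "biological"))
  small_lambda <- glog_transform(big, lambda = 1e-6)
  expect_equal(small_lambda$values, log(big$values), tolerance = 1e-9)
})

test_that("glog at lambda one maps zero to -log 2 and is monotone", {
  v <- matrix(0, 1, 2)
  mt <- make_table(v, c("qc", "biological"))
  out <- glog_transform(mt, lambda = 1)
  expect_equal(out$values[1, 1], log(1 / 2))

  withr::local_seed(18)
  x <- sort(runif(50, 0, 1e5))
  g <- metaboflow:::glog(x, lambda = 123)
  expect_true(all(diff(g) > 0))

  expect_error(glog_transform(mt, lambda = 0), "strictly positive")
})

test_that("lambda selection matches a brute-force grid search", {
  withr::local_seed(19)
  # additive-noise-dominated low-intensity data with a small multiplicative
  # component (the standard two-component error model)
  mu <- runif(80, 5, 50)
  nqc <- 8
  v <- outer(mu, rep(1, nqc)) * matrix(exp(rnorm(80 * nqc, 0, 0.1)), 80) +
    matrix(rnorm(80 * nqc, 0, 5), 80)
  v <- pmax(v, 0)
  v <- cbind(v, mu) # one biological column, ignored by the estimator
  colnames(v) <- NULL
  mt <- make_table(v, c(rep("qc", nqc), "biological"))
  grid <- 10^seq(-2, 4, length.out = 49)
  est <- estimate_glog_lambda(mt, grid = grid)
  # independent exhaustive search re-implementing the relative criterion
  crit <- sapply(grid, function(l) {
    g <- log((v[, 1:nqc] + sqrt(v[, 1:nqc]^2 + l^2)) / 2)
    vv <- apply(g, 1, var)
    mean(abs(vv - mean(vv))) / mean(vv)
  })
  expect_equal(est, grid[which.min(crit)])
  # a finite interior optimum: the additive floor rules out tiny lambda and
  # the multiplicative component rules out huge lambda
  expect_gt(est, min(grid))
  expect_lt(est, max(grid))
})

test_that("multiplicative noise selects a lambda small versus the median", {
  withr::local_seed(20)
  mu <- rlnorm(150, 10, 1)
  v <- outer(mu, rep(1, 6)) * matrix(exp(rnorm(900, 0, 0.1)), 150)
  mt <- make_table(v, c(rep("qc", 6)), groups = rep(NA_character_, 6))
  est <- estimate_glog_lambda(mt)
  expect_lt(est / median(v), 0.1)
})

test_that("degenerate single-value grid returns that lambda", {
  mt <- make_table(matrix(1:4, 2, 2), c("qc", "qc"),
    groups = rep(NA_character_, 2)
  )
  expect_equal(estimate_glog_lambda(mt, grid = 42), 42)
  one_qc <- make_table(matrix(1:2, 1, 2), c("qc", "biological"))
  expect_error(estimate_glog_lambda(one_qc), "2 QC samples")
})

test_that("TPA normalization conserves per-sample totals", {
  v <- cbind(c(1, 1, 2), c(2, 2, 4), c(10, 30, 60))
  mt <- make_table(v, rep("biological", 3))
  unit <- tpa_normalize(mt, "unit_sum")
  expect_equal(unname(unit$values[, 1]), c(0.25, 0.25, 0.5))
  expect_equal(unname(colSums(unit$values)), rep(1, 3), tolerance = 1e-12)

  med <- tpa_normalize(mt, "median_total")
  expect_equal(unname(colSums(med$values)), rep(8, 3)) # median total is 8

  zero <- make_table(cbind(c(0, 0), c(1, 2)), rep("biological", 2),
    assay = "HILIC"
  )
  expect_error(tpa_normalize(zero), "non-positive total")
})

test_that("equal-total samples keep their relative values under TPA", {
  v <- cbind(c(1, 3), c(2, 2))
  mt <- make_table(v, rep("biological", 2))
  out <- tpa_normalize(mt, "unit_sum")
  expect_equal(out$values[1, 1] / out$values[2, 1], 1 / 3)
  expect_equal(out$values[1, 2] / out$values[2, 2], 1)
})
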