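test_that("rank-one data loads entirely on the first component", {
  v <- rbind(c(1, 2, 3, 4), c(2, 4, 6, 8))
  mt <- make_table(v, rep("biological", 4))
  p <- pca_scores(mt, 2)
  expect_equal(p$explained_variance[1], 1, tolerance = 1e-9)
})

test_that("isotropic noise spreads variance evenly across components", {
  withr::local_seed(30)
  v <- matrix(abs(rnorm(2000 * 20, 100, 1)), 2000, 20)
  mt <- make_table(v, rep("biological", 20))
  p <- pca_scores(mt, 19)
  ev <- p$explained_variance
  expect_true(all(diff(ev) <= 1e-12)) # non-increasing
  expect_lt(max(ev) / mean(ev), 1.4)
  expect_lte(sum(ev), 1 + 1e-9)
})

test_that("PCA scores are feature-order invariant up to sign", {
  withr::local_seed(31)
  v <- matrix(rlnorm(200, 5, 1), 20, 10)
  mt <- make_table(v, rep("biological", 10))
  p1 <- pca_scores(mt, 2)
  perm <- sample(20)
  mt2 <- mt[perm, ]
  p2 <- pca_scores(mt2, 2)
  expect_equal(abs(p1$scores$PC1), abs(p2$scores$PC1), tolerance = 1e-9)
  expect_error(
    pca_scores(make_table(matrix(c(1, NA, 3, 4), 2, 2),
      rep("biological", 2)
    )),
    "knn_impute"
  )
})

test_that("t-test handles identical and separated groups", {
  expect_equal(ttest_feature(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_lt(ttest_feature(c(1, 2, 3), c(101, 102, 103)), 1e-4)
  expect_warning(p <- ttest_feature(1, c(1, 2)), "fewer than 2")
  expect_true(is.na(p))
  # zero-variance limits
  expect_equal(ttest_feature(c(5, 5, 5), c(5, 5, 5)), 1)
  expect_equal(ttest_feature(c(5, 5, 5), c(6, 6, 6)), 0)
})

test_that("t-test matches the textbook formulas on random instances", {
  withr::local_seed(32)
  for (i in 1:50) {
    a <- rnorm(sample(3:10, 1), sd = runif(1, 0.5, 2))
    b <- rnorm(sample(3:10, 1), mean = runif(1, -1, 1))
    expect_equal(ttest_feature(a, b, "welch"), oracle_ttest(a, b),
      tolerance = 1e-10
    )
    expect_equal(ttest_feature(a, b, "student"),
      oracle_ttest(a, b, pooled = TRUE),
      tolerance = 1e-10
    )
  }
})

test_that("fold change is the ratio of group means", {
  expect_equal(fold_change(c(110, 130), c(90, 110)), 1.2)
  expect_equal(fold_change(c(1, 2, 3), c(1, 2, 3)), 1)
  a <- c(3, 5, 9)
  b <- c(2, 4, 7)
  expect_equal(fold_change(a, b) * fold_change(b, a), 1)
  expect_error(fold_change(c(1, 2), c(0, 0)), "not positive")
})

test_that("differential calls exclude window and alpha boundaries", {
  cfg <- stats_config()
  expect_true(call_differential(0.01, 1.5, cfg))
  expect_true(call_differential(0.01, 0.5, cfg))
  expect_false(call_differential(0.01, 1.2, cfg)) # FC boundary
  expect_false(call_differential(0.01, 0.8, cfg))
  expect_false(call_differential(0.05, 2, cfg)) # alpha boundary
  expect_false(call_differential(0.2, 3, cfg))
  expect_false(call_differential(NA, 3, cfg))
})

fake_diff <- function(universe, sig, contrast = "A vs B") {
  out <- tibble::tibble(
    feature_id = universe,
    contrast = contrast,
    p_value = ifelse(universe %in% sig, 0.01, 0.5),
    fold_change = ifelse(universe %in% sig, 2, 1),
    log2_fc = log2(fold_change),
    significant = universe %in% sig
  )
  class(out) <- c("metab_diff", class(out))
  out
}

test_that("contrast comparison partitions the significant sets", {
  u <- paste0("m", 1:10)
  a <- fake_diff(u, c("m1", "m2", "m3"), "T vs C")
  b <- fake_diff(u, c("m2", "m3", "m4"), "D vs C")
  cc <- compare_contrasts(a, b)
  expect_setequal(cc$shared, c("m2", "m3"))
  expect_setequal(cc$unique_to_a, "m1")
  expect_setequal(cc$unique_to_b, "m4")
  expect_equal(cc$pct_unique_a + cc$pct_shared_a, 100)

  disjoint <- compare_contrasts(
    fake_diff(u, c("m1", "m2")), fake_diff(u, c("m5"))
  )
  expect_length(disjoint$shared, 0)
  expect_equal(disjoint$pct_unique_a, 100)

  dup <- fake_diff(c(u, "m1"), "m1")
  expect_error(compare_contrasts(dup, fake_diff(c(u, "m1"), "m1")),
    "duplicated")
  expect_error(compare_contrasts(a, fake_diff(paste0("x", 1:10), "x1")),
    "different feature universes")
})

test_that("63 treatment-significant with 12 shared reports 81% unique", {
  u <- sprintf("m%03d", 1:200)
  treat_sig <- u[1:63]
  disease_sig <- c(u[52:63], u[100:160]) # 12 shared
  cc <- compare_contrasts(fake_diff(u, treat_sig), fake_diff(u, disease_sig))
  expect_equal(length(cc$unique_to_a), 51)
  expect_equal(length(cc$shared), 12)
  expect_equal(round(cc$pct_unique_a), 81)
  expect_equal(round(cc$pct_shared_a), 19)
})

test_that("reversion classification follows the sign product rule", {
  res <- classify_reversion(
    c("a", "b", "c"),
    disease_log2fc = c(a = 1, b = 1, c = 1),
    treatment_log2fc = c(a = -0.5, b = 0.5, c = 0)
  )
  expect_identical(res$direction, c("reverted", "exacerbated", "mixed"))
  # antisymmetry under flipping the treatment contrast
  flipped <- classify_reversion(
    c("a", "b"),
    disease_log2fc = c(a = 1, b = 1),
    treatment_log2fc = -c(a = -0.5, b = 0.5)
  )
  expect_identical(flipped$direction, c("exacerbated", "reverted"))
  expect_error(
    classify_reversion("z", c(a = 1), c(a = 1)),
    "missing log2 fold change"
  )
})

test_that("Mann-Whitney exact p for fully separated triples is 0.1", {
  expect_equal(mann_whitney(c(1, 2, 3), c(4, 5, 6)), 0.1)
  expect_equal(mann_whitney(c(1, 2, 3), c(1, 2, 3)), 1)
})

test_that("Mann-Whitney matches full enumeration on random 4v4 draws", {
  withr::local_seed(33)
  for (i in 1:50) {
    a <- round(runif(4, 0, 10), 1)
    b <- round(runif(4, 0, 10), 1)
    expect_equal(mann_whitney(a, b), oracle_mann_whitney(a, b),
      tolerance = 1e-10
    )
  }
  # untied case agrees with the exact rank-sum test
  a <- c(1.2, 3.4, 7.1, 9.9)
  b <- c(2.2, 4.1, 5.5, 8.8)
  expect_equal(
    mann_whitney(a, b),
    stats::wilcox.test(a, b, exact = TRUE)$p.value,
    tolerance = 1e-10
  )
})

test_that("large-sample Mann-Whitney approximates the exact test", {
  withr::local_seed(34)
  a <- rnorm(12)
  b <- rnorm(12, 1)
  p_approx <- mann_whitney(a, b)
  p_ref <- stats::wilcox.test(a, b, exact = TRUE)$p.value
  expect_lt(abs(p_approx - p_ref), 0.02)
})

test_that("delta-delta-Ct fold changes follow the exponent laws", {
  expect_equal(ddct_fold_change(24, 20, 25, 20), 2)
  expect_equal(ddct_fold_change(20, 20, 20, 20), 1)
  base <- ddct_fold_change(24, 20, 25, 20)
  expect_equal(ddct_fold_change(25, 20, 25, 20), base / 2)
})

test_that("run_differential ties tests to glog data and FCs to TPA data", {
  cfg <- sim_config(
    n_features = 60, qc_cv = 0, bio_cv = 0, drift_slope = 0,
    missing_lod_quantile = 0, random_missing_rate = 0, frac_contaminant = 0,
    effects = list(sim_effect("treatment", "DIAB-LAV", "DIAB-V",
      log2fc = 1, features = 1:4
    )),
    seed = 35
  )
  sim <- simulate_feature_table(cfg)
  imp <- knn_impute(run_qc_cascade(sim$table)$table)
  tpa <- tpa_normalize(imp)
  gl <- glog_transform(tpa)
  d <- run_differential(gl, tpa, "DIAB-LAV", "DIAB-V")
  planted <- sim$truth$features$id[sim$truth$features$log2fc_treatment != 0]
  expect_setequal(d$feature_id[d$significant], planted)
  g <- glance(d)
  expect_equal(g$n_significant, 4)
  expect_equal(g$n_up, 4)
})
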