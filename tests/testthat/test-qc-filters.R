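test_that("equilibration removal drops the earliest-injected QCs only", {
  v <- matrix(100, 2, 16)
  roles <- c(rep("qc", 12), rep("biological", 4))
  mt <- make_table(v, roles)
  res <- remove_equilibration_qcs(mt, 5)
  expect_equal(sum(res$table$samples$role == "qc"), 7)
  expect_equal(sum(res$table$samples$role == "biological"), 4)
  expect_identical(res$removed, paste0("S", 1:5))

  expect_identical(remove_equilibration_qcs(mt, 0)$table$samples, mt$samples)
  expect_error(remove_equilibration_qcs(mt, 13), "only 12")
})

test_that("equilibration removal uses injection order, not position", {
  v <- matrix(100, 1, 7)
  mt <- metab_table(
    v <- matrix(100, 1, 7, dimnames = list("F1", paste0("S", 1:7))),
    features = tibble::tibble(
      id = "F1", mz = 100, rt = 60, polarity = "positive", assay = "HILIC"
    ),
    samples = tibble::tibble(
      id = paste0("S", 1:7),
      role = c(rep("qc", 6), "biological"),
      group = c(rep(NA, 6), "A"),
      injection_order = c(20L, 1L, 2L, 3L, 4L, 5L, 6L)
    )
  )
  res <- remove_equilibration_qcs(mt, 5)
  kept_qc <- res$table$samples$id[res$table$samples$role == "qc"]
  expect_identical(kept_qc, "S1") # the injection-20 QC survives
})

test_that("blank ratio filter applies the strict less-than rule", {
  # rows: removed (1900 < 20*100), kept boundary (2000 = 20*100), kept
  v <- rbind(
    c(1900, 1900, 100, 100, 500),
    c(2000, 2000, 100, 100, 500),
    c(3000, 3000, 100, 100, 500)
  )
  roles <- c("qc", "qc", "blank", "blank", "biological")
  mt <- make_table(v, roles)
  res <- filter_blank_ratio(mt, 20)
  expect_identical(res$removed, "F1")
  expect_identical(res$table$features$id, c("F2", "F3"))
})

test_that("all-missing blanks count as zero and features are kept", {
  v <- rbind(c(10, 12, NA, NA, 5), c(8, 9, NA, NA, 5))
  roles <- c("qc", "qc", "blank", "blank", "biological")
  mt <- make_table(v, roles)
  res <- filter_blank_ratio(mt, 20)
  expect_length(res$removed, 0)
})

test_that("features with no observed QC value are removed by the blank filter", {
  v <- rbind(c(NA, NA, 1, 1, 5), c(100, 100, 1, 1, 5))
  roles <- c("qc", "qc", "blank", "blank", "biological")
  mt <- make_table(v, roles)
  expect_identical(filter_blank_ratio(mt, 20)$removed, "F1")
})

test_that("missing blanks are required for the blank filter", {
  v <- matrix(10, 2, 3)
  mt <- make_table(v, c("qc", "qc", "biological"))
  expect_error(filter_blank_ratio(mt, 20), "disable")
})

test_that("sample missingness filter is strict and role-agnostic", {
  v <- matrix(1, 10, 3)
  v[1:6, 2] <- NA # 6/10 missing -> removed
  v[1:5, 3] <- NA # exactly 5/10 -> kept
  mt <- make_table(v, c("qc", "biological", "blank"))
  res <- filter_sample_missingness(mt, 0.5)
  expect_identical(res$removed, "S2")
  expect_identical(res$table$samples$id, c("S1", "S3"))

  full <- make_table(matrix(1, 3, 3), rep("biological", 3))
  expect_length(filter_sample_missingness(full, 0.5)$removed, 0)
})

test_that("QC RSD filter removes high-RSD and unassessable features", {
  v <- rbind(
    c(90, 100, 110, 50), # RSD 10% -> kept
    c(50, 100, 150, 50), # RSD 50% -> removed
    c(100, 100, 100, 50), # RSD 0 -> kept
    c(100, NA, NA, 50) # single QC observation -> removed
  )
  mt <- make_table(v, c("qc", "qc", "qc", "biological"))
  res <- filter_qc_rsd(mt, 30)
  expect_setequal(res$removed, c("F2", "F4"))
  rsd <- qc_rsd_values(mt)
  expect_equal(unname(rsd[1]), 10)
  expect_equal(unname(rsd[2]), 50)
})

test_that("QC detection filter boundary: exactly 90% survives", {
  v <- matrix(1, 3, 11)
  v[1, 1:2] <- NA # 8/10 -> removed
  v[2, 1] <- NA # 9/10 -> kept
  mt <- make_table(v, c(rep("qc", 10), "biological"))
  res <- filter_qc_detection(mt, 0.90)
  expect_identical(res$removed, "F1")
})

test_that("overall detection filter boundary: exactly 50% survives", {
  v <- matrix(1, 3, 10)
  v[1, 1:6] <- NA # 4/10 -> removed
  v[2, 1:5] <- NA # 5/10 -> kept
  mt <- make_table(v, c(rep("biological", 8), "qc", "qc"))
  res <- filter_overall_detection(mt, 0.5)
  expect_identical(res$removed, "F1")

  v[3, ] <- NA # all-missing feature
  mt2 <- make_table(v, c(rep("biological", 8), "qc", "qc"))
  expect_setequal(filter_overall_detection(mt2, 0.5)$removed, c("F1", "F3"))
})

test_that("feature filters are idempotent", {
  withr::local_seed(21)
  v <- matrix(rlnorm(200, 5, 1), 20, 10)
  v[sample(200, 30)] <- NA
  roles <- c(rep("qc", 4), rep("biological", 4), rep("blank", 2))
  mt <- make_table(v, roles)
  for (f in list(
    function(m) filter_blank_ratio(m, 20),
    function(m) filter_qc_rsd(m, 30),
    function(m) filter_qc_detection(m, 0.9),
    function(m) filter_overall_detection(m, 0.5),
    function(m) filter_sample_missingness(m, 0.5)
  )) {
    once <- f(mt)
    twice <- f(once$table)
    expect_length(twice$removed, 0)
    expect_identical(twice$table$values, once$table$values)
  }
})

test_that("the cascade reconciles counts and respects stage order", {
  mt <- make_cascade_toy()
  res <- run_qc_cascade(mt, qc_config())
  stages <- tidy(res$report)
  expect_identical(
    stages$stage,
    c(
      "equilibration", "blank_ratio", "sample_missingness", "qc_rsd",
      "qc_detection", "overall_detection"
    )
  )
  g <- glance(res$report)
  expect_equal(g$n_features_in - sum(stages$n_removed[stages$axis == "feature"]),
    g$n_features_out)
  expect_equal(g$n_samples_in - sum(stages$n_removed[stages$axis == "sample"]),
    g$n_samples_out)
  expect_setequal(res$table$features$id, c("good1", "good2"))
})

test_that("disabling all stages is the identity with an empty report", {
  mt <- make_cascade_toy()
  res <- run_qc_cascade(mt, qc_config(stages = character(0)))
  expect_identical(res$table$values, mt$values)
  expect_equal(nrow(res$report$stages), 0)
})

test_that("a clean zero-noise table passes the cascade untouched", {
  cfg <- sim_config(
    n_features = 40, qc_cv = 0, bio_cv = 0, drift_slope = 0,
    missing_lod_quantile = 0, random_missing_rate = 0,
    frac_contaminant = 0, effects = list(), seed = 10
  )
  sim <- simulate_feature_table(cfg)
  res <- run_qc_cascade(sim$table)
  expect_identical(res$table$features$id, sim$table$features$id)
})

test_that("blank filter removes nearly all planted contaminants", {
  cfg <- sim_config(n_features = 500, frac_contaminant = 0.1, seed = 12)
  sim <- simulate_feature_table(cfg)
  contam <- sim$truth$features$id[sim$truth$features$class == "contaminant"]
  res <- run_qc_cascade(sim$table)
  removed_blank <- tidy(res$report)$removed[[2]]
  expect_gte(mean(contam %in% removed_blank), 0.95)
})
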