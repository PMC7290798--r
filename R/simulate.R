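#' Simulation configuration
#'
#' Describes a synthetic untargeted LC-MS batch: the run sequence (lead QC
#' block, QC every `qc_interval`-th injection, tail QCs, blanks), per-feature
#' baseline intensities, technical and biological noise, injection-order
#' drift on the pooled QCs, intensity-dependent and random missingness,
#' contaminant features visible in blanks, per-sample dilution factors, and
#' planted group effects for recovery testing.
#'
#' Defaults mirror a three-group rodent heart study design: groups `ND-V`
#' (non-diabetic vehicle), `DIAB-V` (diabetic vehicle) and `DIAB-LAV`
#' (diabetic treated) with n = 6 each; ten lead QC injections with a blank as
#' the 6th injection, a QC every sixth injection thereafter, and a blank plus
#' two QCs closing the batch. Noise defaults (`qc_cv` 10%, `bio_cv` 25%) are
#' documented stand-ins typical of pooled-QC repeatability and rodent tissue
#' variability, not measured values.
#'
#' @param n_features Number of features to simulate.
#' @param groups Named integer vector: biological group sizes.
#' @param n_lead_qc,qc_interval,n_tail_qc,n_blanks Run-sequence design.
#' @param qc_cv Technical coefficient of variation of pooled-QC injections.
#' @param bio_cv Biological coefficient of variation within a group.
#' @param drift_slope Per-injection multiplicative drift applied to QCs.
#' @param missing_lod_quantile Per-feature quantile below which values are
#'   censored to missing (intensity-dependent missingness).
#' @param random_missing_rate Additional missing-completely-at-random rate.
#' @param frac_contaminant Fraction of features of non-biological origin
#'   (present in blanks at sample-like level).
#' @param effects List of [sim_effect()] planted group effects. The default
#'   plants a broad disease effect (25% of features, |log2 FC| = 1, mixed
#'   sign, `DIAB-V` vs `ND-V`) and a small mostly-upward treatment effect
#'   (3.5% of features, log2 FC = 1, 95% positive, `DIAB-LAV` vs `DIAB-V`).
#' @param dilution_range Per-sample true dilution factors are drawn
#'   log-uniformly from this interval.
#' @param assay `"HILIC"` or `"LIPIDS"`; fixes the m/z range (70-1050 or
#'   150-2000 Th) and polarity of the simulated features.
#' @param baseline_meanlog,baseline_sdlog Log-normal baseline intensity
#'   parameters.
#' @param plant_annotatable Place the first features at exact adduct m/z
#'   values of the bundled compound list, for annotation recovery tests.
#' @param seed Integer seed; identical config + seed gives identical output.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_features = 1000,
                       groups = c("ND-V" = 6, "DIAB-V" = 6, "DIAB-LAV" = 6),
                       n_lead_qc = 10, qc_interval = 6, n_tail_qc = 2,
                       n_blanks = 2, qc_cv = 0.10, bio_cv = 0.25,
                       drift_slope = 0.002, missing_lod_quantile = 0.05,
                       random_missing_rate = 0.02, frac_contaminant = 0.05,
                       effects = default_effects(),
                       dilution_range = c(0.7, 1.4), assay = "HILIC",
                       baseline_meanlog = log(1e5), baseline_sdlog = 1.2,
                       plant_annotatable = FALSE, seed = 1L) {
  cfg <- list(
    n_features = as.integer(n_features), groups = groups,
    n_lead_qc = as.integer(n_lead_qc), qc_interval = as.integer(qc_interval),
    n_tail_qc = as.integer(n_tail_qc), n_blanks = as.integer(n_blanks),
    qc_cv = qc_cv, bio_cv = bio_cv, drift_slope = drift_slope,
    missing_lod_quantile = missing_lod_quantile,
    random_missing_rate = random_missing_rate,
    frac_contaminant = frac_contaminant, effects = effects,
    dilution_range = dilution_range, assay = assay,
    baseline_meanlog = baseline_meanlog, baseline_sdlog = baseline_sdlog,
    plant_annotatable = isTRUE(plant_annotatable), seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  fracs <- c(
    cfg$qc_cv, cfg$bio_cv, cfg$missing_lod_quantile,
    cfg$random_missing_rate, cfg$frac_contaminant
  )
  if (any(fracs < 0) || any(c(
    cfg$missing_lod_quantile, cfg$random_missing_rate, cfg$frac_contaminant
  ) > 1)) {
    stop("simulation fractions must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$qc_interval < 2) stop("qc_interval must be >= 2", call. = FALSE)
  if (!length(cfg$groups) || is.null(names(cfg$groups))) {
    stop("`groups` must be a non-empty named vector of group sizes",
      call. = FALSE
    )
  }
  if (!cfg$assay %in% c("HILIC", "LIPIDS")) {
    stop("assay must be 'HILIC' or 'LIPIDS'", call. = FALSE)
  }
  if (cfg$n_features < 1) stop("n_features must be positive", call. = FALSE)
  cfg
}

#' Planted group effect
#'
#' Declares that a random fraction of features carries a multiplicative
#' `2^log2fc` shift in group `group_a` relative to `group_b` (which stays at
#' baseline). `log2fc` may be a single value, a vector sampled from, or a
#' function `n -> numeric(n)` drawing per-feature effect sizes.
#'
#' @param name Contrast label, e.g. `"disease"`.
#' @param group_a Group name(s) receiving the shift. A disease effect is
#'   naturally shared by every diseased group (treated or not), so `group_a`
#'   may name several groups; the shift then cancels in any contrast between
#'   two shifted groups.
#' @param group_b Reference group name (stays at baseline); recorded for the
#'   contrast label and ground truth.
#' @param frac Fraction of features affected (ignored when `features` given).
#' @param log2fc Effect size(s) on the log2 scale.
#' @param features Optional explicit feature indices to affect, for
#'   deterministic planted structures; `NULL` draws them at random.
#' @return A `sim_effect` list.
#' @export
sim_effect <- function(name, group_a, group_b, frac = 0, log2fc = 1,
                       features = NULL) {
  stopifnot(frac >= 0, frac <= 1)
  structure(
    list(
      name = name, group_a = group_a, group_b = group_b,
      frac = frac, log2fc = log2fc, features = features
    ),
    class = "sim_effect"
  )
}

#' @rdname sim_config
#' @export
default_effects <- function() {
  list(
    # diabetes shifts both diabetic groups relative to the non-diabetic one
    sim_effect("disease", c("DIAB-V", "DIAB-LAV"), "ND-V",
      frac = 0.25,
      log2fc = function(n) sample(c(-1, 1), n, replace = TRUE)
    ),
    sim_effect("treatment", "DIAB-LAV", "DIAB-V",
      frac = 0.035,
      log2fc = function(n) {
        sample(c(1, -1), n, replace = TRUE, prob = c(0.95, 0.05))
      }
    )
  )
}

assay_mz_range <- function(assay) {
  switch(assay,
    HILIC = c(70, 1050),
    LIPIDS = c(150, 2000),
    stop("unknown assay '", assay, "'", call. = FALSE)
  )
}

#' Generate a run sequence
#'
#' Builds the injection order of a batch: the lead QC block (with the first
#' blank inserted mid-block when blanks are requested), biological samples in
#' seeded random order with a pooled QC at every `qc_interval`-th injection,
#' then the closing blank and tail QCs. With the defaults the batch starts
#' with 5 QCs, a blank and 5 more QCs, and ends blank, QC, QC.
#'
#' @param config A [sim_config()].
#' @return A tibble of samples in injection order: `id`, `role`, `group`,
#'   `injection_order` (consecutive from 1).
#' @export
generate_run_sequence <- function(config) {
  cfg <- validate_sim_config(config)
  n_bio <- sum(cfg$groups)
  if (n_bio < 1) stop("no biological samples configured", call. = FALSE)

  bio_ids <- unlist(purrr::imap(as.list(cfg$groups), function(n, g) {
    paste0(g, "_", seq_len(n))
  }), use.names = FALSE)
  bio_groups <- rep(names(cfg$groups), times = cfg$groups)
  ord <- withr::with_seed(cfg$seed, sample.int(n_bio))
  bio_ids <- bio_ids[ord]
  bio_groups <- bio_groups[ord]

  roles <- character(0)
  # lead block: first blank mid-way through the lead QCs
  lead <- rep("qc", cfg$n_lead_qc)
  if (cfg$n_blanks >= 1 && cfg$n_lead_qc > 0) {
    at <- floor(cfg$n_lead_qc / 2)
    lead <- append(lead, "blank", after = at)
  } else if (cfg$n_blanks >= 1) {
    lead <- "blank"
  }
  roles <- c(roles, lead)

  since_qc <- 0L
  left <- n_bio
  while (left > 0) {
    if (since_qc == cfg$qc_interval - 1L) {
      roles <- c(roles, "qc")
      since_qc <- 0L
    } else {
      roles <- c(roles, "biological")
      since_qc <- since_qc + 1L
      left <- left - 1L
    }
  }

  n_blank_left <- max(0L, cfg$n_blanks - 1L)
  roles <- c(roles, rep("blank", n_blank_left), rep("qc", cfg$n_tail_qc))

  n_qc <- sum(roles == "qc")
  ids <- character(length(roles))
  grps <- rep(NA_character_, length(roles))
  ids[roles == "qc"] <- sprintf("QC%02d", seq_len(n_qc))
  ids[roles == "blank"] <- sprintf("BLANK%02d", seq_len(sum(roles == "blank")))
  ids[roles == "biological"] <- bio_ids
  grps[roles == "biological"] <- bio_groups

  tibble::tibble(
    id = ids, role = roles, group = grps,
    injection_order = seq_along(roles)
  )
}

# Per-feature per-group log2 effects, drawn per config (seeded by caller).
draw_effects <- function(cfg, feature_ids, eligible) {
  groups <- names(cfg$groups)
  eff_mat <- matrix(0, length(feature_ids), length(groups),
    dimnames = list(feature_ids, groups)
  )
  truth_cols <- list()
  for (eff in cfg$effects) {
    if (!all(c(eff$group_a, eff$group_b) %in% groups)) {
      stop("effect '", eff$name, "' names an unknown group", call. = FALSE)
    }
    if (!is.null(eff$features)) {
      aff <- as.integer(eff$features)
      stopifnot(all(aff >= 1), all(aff <= length(feature_ids)))
    } else {
      n_aff <- round(eff$frac * length(feature_ids))
      pool <- which(eligible)
      n_aff <- min(n_aff, length(pool))
      aff <- if (n_aff > 0) pool[sample.int(length(pool), n_aff)] else integer(0)
    }
    lfc <- numeric(length(feature_ids))
    if (length(aff)) {
      sizes <- if (is.function(eff$log2fc)) {
        eff$log2fc(length(aff))
      } else if (length(eff$log2fc) == 1) {
        rep(eff$log2fc, length(aff))
      } else {
        sample(eff$log2fc, length(aff), replace = TRUE)
      }
      lfc[aff] <- sizes
      for (g in eff$group_a) {
        eff_mat[aff, g] <- eff_mat[aff, g] + sizes
      }
    }
    truth_cols[[paste0("log2fc_", eff$name)]] <- lfc
  }
  list(group_log2 = eff_mat, truth_cols = truth_cols)
}

#' Simulate a feature table with ground truth
#'
#' Draws per-feature log-normal baselines, applies planted group effects
#' (`2^log2fc` on the affected group), per-sample dilution factors
#' (log-uniform), multiplicative log-normal biological noise, pooled-QC
#' technical noise with geometric injection-order drift, blank signal for
#' contaminant features only, then censors values below the per-feature
#' `missing_lod_quantile` and adds random missingness. Fully deterministic
#' given the config (which carries the seed).
#'
#' @param config A [sim_config()].
#' @return A list with elements `table` (a [metab_table()]) and `truth` (a
#'   `sim_truth`: per-feature class and planted log2 effects, per-sample true
#'   dilution factors, drift parameters).
#' @export
simulate_feature_table <- function(config) {
  cfg <- validate_sim_config(config)
  run <- generate_run_sequence(cfg)

  withr::with_seed(cfg$seed + 1L, {
    nf <- cfg$n_features
    fid <- sprintf("M%04d", seq_len(nf))
    mzr <- assay_mz_range(cfg$assay)
    mz <- stats::runif(nf, mzr[1], mzr[2])
    rt <- stats::runif(nf, 30, 840)
    polarity <- sample(c("positive", "negative"), nf, replace = TRUE)

    if (cfg$plant_annotatable) {
      planted <- plant_adduct_features(nf, cfg$assay)
      k <- nrow(planted)
      if (k > 0) {
        mz[seq_len(k)] <- planted$mz
        polarity[seq_len(k)] <- planted$polarity
      }
    }

    n_contam <- round(cfg$frac_contaminant * nf)
    contam <- rep(FALSE, nf)
    if (n_contam > 0) contam[sample.int(nf, n_contam)] <- TRUE

    eff <- draw_effects(cfg, fid, eligible = !contam)
    baseline <- stats::rlnorm(nf, cfg$baseline_meanlog, cfg$baseline_sdlog)

    is_bio <- run$role == "biological"
    is_qc <- run$role == "qc"
    is_blank <- run$role == "blank"
    ns <- nrow(run)

    dilution <- rep(NA_real_, ns)
    dilution[is_bio] <- exp(stats::runif(
      sum(is_bio), log(cfg$dilution_range[1]), log(cfg$dilution_range[2])
    ))
    dilution[is_qc] <- 1

    sdlog_bio <- sqrt(log(1 + cfg$bio_cv^2))
    sdlog_qc <- sqrt(log(1 + cfg$qc_cv^2))

    # noise-free expected value per biological sample (baseline x group effect)
    expected <- matrix(baseline, nf, ns)
    for (j in which(is_bio)) {
      g <- run$group[j]
      expected[, j] <- baseline * 2^eff$group_log2[, g]
    }
    pooled_mean <- rowMeans(
      expected[, is_bio, drop = FALSE] *
        rep(dilution[is_bio], each = nf)
    )

    values <- matrix(NA_real_, nf, ns, dimnames = list(fid, run$id))
    for (j in seq_len(ns)) {
      if (is_bio[j]) {
        noise <- if (cfg$bio_cv > 0) {
          exp(stats::rnorm(nf, 0, sdlog_bio))
        } else {
          rep(1, nf)
        }
        values[, j] <- expected[, j] * dilution[j] * noise
      } else if (is_qc[j]) {
        noise <- if (cfg$qc_cv > 0) {
          exp(stats::rnorm(nf, 0, sdlog_qc))
        } else {
          rep(1, nf)
        }
        drift <- (1 + cfg$drift_slope)^run$injection_order[j]
        values[, j] <- pooled_mean * noise * drift
      } else {
        # blanks: contaminants show up at sample-like level, others absent
        v <- rep(NA_real_, nf)
        if (any(contam)) {
          noise <- if (cfg$qc_cv > 0) {
            exp(stats::rnorm(sum(contam), 0, sdlog_qc))
          } else {
            rep(1, sum(contam))
          }
          v[contam] <- pooled_mean[contam] * noise
        }
        values[, j] <- v
      }
    }

    # intensity-dependent missingness: censor below per-feature LOD quantile
    if (cfg$missing_lod_quantile > 0) {
      meas <- is_bio | is_qc
      lod <- apply(values[, meas, drop = FALSE], 1, stats::quantile,
        probs = cfg$missing_lod_quantile, na.rm = TRUE, names = FALSE
      )
      censor <- values < lod & rep(meas, each = nf)
      values[which(censor)] <- NA_real_
    }
    if (cfg$random_missing_rate > 0) {
      meas_cells <- which(rep(is_bio | is_qc, each = nf))
      drop <- meas_cells[
        stats::runif(length(meas_cells)) < cfg$random_missing_rate
      ]
      values[drop] <- NA_real_
    }

    features <- tibble::tibble(
      id = fid, mz = mz, rt = rt, polarity = polarity, assay = cfg$assay
    )
    table <- metab_table(values, features, run)

    any_effect <- rep(FALSE, nf)
    for (col in eff$truth_cols) any_effect <- any_effect | (col != 0)
    feature_truth <- tibble::tibble(
      id = fid,
      class = dplyr::case_when(
        contam ~ "contaminant",
        any_effect ~ "differential",
        TRUE ~ "null"
      ),
      baseline = baseline,
      !!!eff$truth_cols
    )
    truth <- structure(
      list(
        features = feature_truth,
        samples = tibble::tibble(id = run$id, dilution = dilution),
        drift_slope = cfg$drift_slope,
        config = cfg
      ),
      class = "sim_truth"
    )
    list(table = table, truth = truth)
  })
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("<sim_truth>", nrow(x$features), "features:")
  print(table(x$features$class))
  invisible(x)
}
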