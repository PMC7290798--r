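#' QC filter configuration
#'
#' Thresholds for the quality-assurance cascade. All boundary comparisons
#' are strict, exactly as the filters are conventionally stated: a feature at
#' exactly 20x the blank mean, exactly 30% RSD, exactly 90% QC detection or
#' exactly 50% overall detection survives.
#'
#' @param n_equilibration_qc Number of lead QC injections used to equilibrate
#'   the system, removed before any filtering (default 5).
#' @param blank_ratio Remove a feature when its mean QC intensity is less
#'   than `blank_ratio` times its mean blank intensity (default 20).
#' @param max_sample_missing_frac Remove any sample (any role) whose missing
#'   fraction exceeds this (default 0.5, strict `>`).
#' @param max_qc_rsd_pct Remove features whose pooled-QC relative standard
#'   deviation exceeds this percentage (default 30, strict `>`).
#' @param min_qc_detection_rate Remove features detected in less than this
#'   fraction of QC injections (default 0.90, strict `<`).
#' @param min_overall_detection_rate Remove features detected in less than
#'   this fraction of all remaining samples (default 0.50, strict `<`).
#' @param overall_detection_bio_only Restrict the overall detection-rate
#'   filter to biological samples (default `FALSE`: all roles count).
#' @param stages Which stages [run_qc_cascade()] executes, in order.
#' @return A `qc_config` list.
#' @export
qc_config <- function(n_equilibration_qc = 5, blank_ratio = 20,
                      max_sample_missing_frac = 0.5, max_qc_rsd_pct = 30,
                      min_qc_detection_rate = 0.90,
                      min_overall_detection_rate = 0.50,
                      overall_detection_bio_only = FALSE,
                      stages = c(
                        "equilibration", "blank_ratio", "sample_missingness",
                        "qc_rsd", "qc_detection", "overall_detection"
                      )) {
  stopifnot(
    blank_ratio > 0, max_qc_rsd_pct > 0,
    max_sample_missing_frac > 0, max_sample_missing_frac <= 1,
    min_qc_detection_rate > 0, min_qc_detection_rate <= 1,
    min_overall_detection_rate > 0, min_overall_detection_rate <= 1
  )
  structure(
    list(
      n_equilibration_qc = as.integer(n_equilibration_qc),
      blank_ratio = blank_ratio,
      max_sample_missing_frac = max_sample_missing_frac,
      max_qc_rsd_pct = max_qc_rsd_pct,
      min_qc_detection_rate = min_qc_detection_rate,
      min_overall_detection_rate = min_overall_detection_rate,
      overall_detection_bio_only = isTRUE(overall_detection_bio_only),
      stages = stages
    ),
    class = "qc_config"
  )
}

drop_samples <- function(mt, ids) {
  if (!length(ids)) return(mt)
  keep <- !(mt$samples$id %in% ids)
  mt[, which(keep)]
}

drop_features <- function(mt, ids) {
  if (!length(ids)) return(mt)
  keep <- !(mt$features$id %in% ids)
  mt[which(keep), ]
}

#' Remove equilibration QC injections
#'
#' The first QC injections of a batch equilibrate the analytical system and
#' are discarded before any QC statistic is computed. The `n` QC samples with
#' the lowest injection order are removed; biological and blank samples are
#' untouched.
#'
#' @param mt A [metab_table()].
#' @param n Number of lead QCs to drop.
#' @return A list with `table` (the reduced `metab_table`) and `removed`
#'   (character vector of removed sample ids).
#' @export
remove_equilibration_qcs <- function(mt, n = 5) {
  qc <- mt$samples[mt$samples$role == "qc", , drop = FALSE]
  if (n > nrow(qc)) {
    stop("cannot remove ", n, " equilibration QCs: only ", nrow(qc),
      " QC samples present",
      call. = FALSE
    )
  }
  removed <- character(0)
  if (n > 0) {
    removed <- qc$id[order(qc$injection_order)][seq_len(n)]
  }
  list(table = drop_samples(mt, removed), removed = as.character(removed))
}

#' Blank ratio filter
#'
#' Removes features of likely non-biological origin: a feature is dropped
#' when its mean QC intensity (missing values excluded) is less than `ratio`
#' times its mean blank intensity (missing blank values count as zero — a
#' blank with no peak is true absence). Features with no observed QC value
#' are removed.
#'
#' @param mt A [metab_table()].
#' @param ratio Required QC/blank mean ratio (default 20, strict `<`).
#' @return A list with `table` and `removed` (feature ids).
#' @export
filter_blank_ratio <- function(mt, ratio = 20) {
  qc_cols <- mt$samples$role == "qc"
  blank_cols <- mt$samples$role == "blank"
  if (!any(qc_cols)) stop("no QC samples in table", call. = FALSE)
  if (!any(blank_cols)) {
    stop("no blank samples in table; disable the blank_ratio stage explicitly",
      call. = FALSE
    )
  }
  qc_mean <- rowMeans(mt$values[, qc_cols, drop = FALSE], na.rm = TRUE)
  blanks <- mt$values[, blank_cols, drop = FALSE]
  blanks[is.na(blanks)] <- 0
  blank_mean <- rowMeans(blanks)
  # all-missing QC rows give NaN means: no QC evidence, remove
  bad <- is.nan(qc_mean) | qc_mean < ratio * blank_mean
  removed <- mt$features$id[bad]
  list(table = drop_features(mt, removed), removed = as.character(removed))
}

#' Sample missingness filter
#'
#' Excludes any sample (biological, QC or blank) whose fraction of missing
#' values over the current features exceeds `max_frac` (strict `>`).
#'
#' @param mt A [metab_table()].
#' @param max_frac Maximum tolerated missing fraction (default 0.5).
#' @return A list with `table` and `removed` (sample ids).
#' @export
filter_sample_missingness <- function(mt, max_frac = 0.5) {
  frac <- colMeans(is.na(mt$values))
  removed <- mt$samples$id[frac > max_frac]
  list(table = drop_samples(mt, removed), removed = as.character(removed))
}

#' Pooled-QC RSD filter
#'
#' Computes each feature's relative standard deviation (100 x sd / mean,
#' sample standard deviation, raw pre-normalization scale) over its observed
#' pooled-QC intensities and removes features with RSD above `max_rsd_pct`
#' (strict `>`). Features with fewer than two observed QC values cannot be
#' assessed and are removed.
#'
#' @param mt A [metab_table()].
#' @param max_rsd_pct Maximum tolerated QC RSD, percent (default 30).
#' @return A list with `table` and `removed` (feature ids).
#' @export
filter_qc_rsd <- function(mt, max_rsd_pct = 30) {
  qc_cols <- mt$samples$role == "qc"
  if (!any(qc_cols)) stop("no QC samples in table", call. = FALSE)
  qc <- mt$values[, qc_cols, drop = FALSE]
  n_obs <- rowSums(!is.na(qc))
  rsd <- qc_rsd_values(mt)
  bad <- n_obs < 2 | is.na(rsd) | rsd > max_rsd_pct
  removed <- mt$features$id[bad]
  list(table = drop_features(mt, removed), removed = as.character(removed))
}

#' Per-feature pooled-QC RSD values
#'
#' @param mt A [metab_table()].
#' @return Named numeric vector of RSD percentages (NA where fewer than two
#'   observed QC values or zero mean).
#' @export
qc_rsd_values <- function(mt) {
  qc <- mt$values[, mt$samples$role == "qc", drop = FALSE]
  apply(qc, 1, function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2) return(NA_real_)
    m <- mean(x)
    if (m == 0) return(NA_real_)
    100 * stats::sd(x) / m
  })
}

#' QC detection-rate filter
#'
#' Removes features detected (non-missing) in less than `min_rate` of the QC
#' injections (strict `<`).
#'
#' @param mt A [metab_table()].
#' @param min_rate Minimum QC detection fraction (default 0.90).
#' @return A list with `table` and `removed` (feature ids).
#' @export
filter_qc_detection <- function(mt, min_rate = 0.90) {
  qc_cols <- mt$samples$role == "qc"
  if (!any(qc_cols)) stop("no QC samples in table", call. = FALSE)
  rate <- rowMeans(!is.na(mt$values[, qc_cols, drop = FALSE]))
  removed <- mt$features$id[rate < min_rate]
  list(table = drop_features(mt, removed), removed = as.character(removed))
}

#' Overall detection-rate filter
#'
#' Removes features detected in less than `min_rate` of all remaining
#' samples (strict `<`). By default all roles count; set `bio_only = TRUE`
#' to evaluate over biological samples only.
#'
#' @param mt A [metab_table()].
#' @param min_rate Minimum detection fraction (default 0.50).
#' @param bio_only Evaluate over biological samples only.
#' @return A list with `table` and `removed` (feature ids).
#' @export
filter_overall_detection <- function(mt, min_rate = 0.50, bio_only = FALSE) {
  cols <- if (bio_only) mt$samples$role == "biological" else
    rep(TRUE, ncol(mt$values))
  rate <- rowMeans(!is.na(mt$values[, cols, drop = FALSE]))
  removed <- mt$features$id[rate < min_rate]
  list(table = drop_features(mt, removed), removed = as.character(removed))
}

#' Run the full QC filter cascade
#'
#' Executes, in order: equilibration-QC removal, blank ratio filter, sample
#' missingness filter, pooled-QC RSD filter, QC detection-rate filter and
#' overall detection-rate filter, recording every stage (removed ids and
#' parameters) in a [write_report()]-serializable provenance report. Filters
#' evaluate raw (pre-normalization) intensities; normalization belongs
#' downstream.
#'
#' @param mt A [metab_table()].
#' @param config A [qc_config()]; its `stages` element selects and orders
#'   the stages, so any stage can be disabled.
#' @return A list with `table` (filtered `metab_table`) and `report`
#'   (a `filter_report`).
#' @export
run_qc_cascade <- function(mt, config = qc_config()) {
  report <- new_filter_report(nrow(mt$values), ncol(mt$values))
  for (stage in config$stages) {
    res <- switch(stage,
      equilibration = {
        r <- remove_equilibration_qcs(mt, config$n_equilibration_qc)
        list(r = r, axis = "sample", params = list(n = config$n_equilibration_qc))
      },
      blank_ratio = {
        r <- filter_blank_ratio(mt, config$blank_ratio)
        list(r = r, axis = "feature", params = list(ratio = config$blank_ratio))
      },
      sample_missingness = {
        r <- filter_sample_missingness(mt, config$max_sample_missing_frac)
        list(
          r = r, axis = "sample",
          params = list(max_frac = config$max_sample_missing_frac)
        )
      },
      qc_rsd = {
        r <- filter_qc_rsd(mt, config$max_qc_rsd_pct)
        list(
          r = r, axis = "feature",
          params = list(max_rsd_pct = config$max_qc_rsd_pct)
        )
      },
      qc_detection = {
        r <- filter_qc_detection(mt, config$min_qc_detection_rate)
        list(
          r = r, axis = "feature",
          params = list(min_rate = config$min_qc_detection_rate)
        )
      },
      overall_detection = {
        r <- filter_overall_detection(
          mt, config$min_overall_detection_rate,
          bio_only = config$overall_detection_bio_only
        )
        list(
          r = r, axis = "feature",
          params = list(
            min_rate = config$min_overall_detection_rate,
            bio_only = config$overall_detection_bio_only
          )
        )
      },
      stop("unknown QC stage '", stage, "'", call. = FALSE)
    )
    mt <- res$r$table
    report <- add_stage(report, stage, res$axis, res$r$removed, res$params)
  }
  list(table = mt, report = report)
}
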