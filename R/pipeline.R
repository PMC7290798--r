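#' Pipeline configuration
#'
#' Bundles the stage configurations of the end-to-end analysis: simulation
#' (or input paths), QC filtering, preprocessing, statistics, contrasts and
#' annotation. The default contrasts mirror a disease contrast (diabetic
#' vehicle vs non-diabetic vehicle) and a treatment contrast (treated
#' diabetic vs diabetic vehicle).
#'
#' @param sim A [sim_config()].
#' @param qc A [qc_config()].
#' @param knn_k Imputation neighbours.
#' @param pqn_reference Reference spectrum for [pqn_normalize()].
#' @param glog_lambda Numeric glog parameter, or `NULL` to select it from
#'   the pooled QCs per branch.
#' @param tpa_rescale Rescaling mode for [tpa_normalize()].
#' @param stats A [stats_config()].
#' @param contrasts Named list of `c(group_a, group_b)` pairs; the first is
#'   treated as the disease contrast and the second as the treatment
#'   contrast for reversion classification.
#' @param annotate Run putative annotation on the filtered table.
#' @param ppm_tol Named ppm tolerances per assay for annotation.
#' @param seed Global seed; overrides `sim$seed`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(), qc = qc_config(),
                            knn_k = 5, pqn_reference = "qc_median",
                            glog_lambda = NULL,
                            tpa_rescale = "median_total",
                            stats = stats_config(),
                            contrasts = list(
                              disease = c("DIAB-V", "ND-V"),
                              treatment = c("DIAB-LAV", "DIAB-V")
                            ),
                            annotate = TRUE,
                            ppm_tol = c(HILIC = 12, LIPIDS = 14),
                            seed = NULL) {
  if (!is.null(seed)) sim$seed <- as.integer(seed)
  structure(
    list(
      sim = validate_sim_config(sim), qc = qc, knn_k = knn_k,
      pqn_reference = pqn_reference, glog_lambda = glog_lambda,
      tpa_rescale = tpa_rescale, stats = stats, contrasts = contrasts,
      annotate = isTRUE(annotate), ppm_tol = ppm_tol
    ),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Every threshold of the pipeline is a named key; recognised top-level
#' sections are `sim`, `qc`, `stats` plus the scalar preprocessing keys of
#' [pipeline_config()]. Unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  take <- function(lst, fun) {
    if (is.null(lst)) return(fun())
    known <- names(formals(fun))
    bad <- setdiff(names(lst), known)
    if (length(bad)) {
      stop("unknown config key: '", bad[1], "'", call. = FALSE)
    }
    if (!is.null(lst$groups)) lst$groups <- unlist(lst$groups)
    do.call(fun, lst)
  }
  sim <- take(raw$sim, sim_config)
  qc <- take(raw$qc, qc_config)
  stats <- take(raw$stats, stats_config)
  top <- raw[setdiff(names(raw), c("sim", "qc", "stats"))]
  known <- setdiff(
    names(formals(pipeline_config)), c("sim", "qc", "stats")
  )
  bad <- setdiff(names(top), known)
  if (length(bad)) stop("unknown config key: '", bad[1], "'", call. = FALSE)
  if (!is.null(top$contrasts)) {
    top$contrasts <- lapply(top$contrasts, unlist)
  }
  if (!is.null(top$ppm_tol)) top$ppm_tol <- unlist(top$ppm_tol)
  do.call(pipeline_config, c(list(sim = sim, qc = qc, stats = stats), top))
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
      call. = FALSE
    )
  })
}

#' Run the end-to-end pipeline on synthetic data
#'
#' Reproduces the full analysis shape on a simulated batch: simulate -> QC
#' filter cascade -> imputation -> branch A (PQN, glog) with PCA -> branch B
#' (TPA, glog for the tests, raw TPA for fold changes) -> differential calls
#' per contrast -> contrast comparison with reversion classification ->
#' putative annotation -> summary. Every intermediate table is written under
#' `out_dir` so each stage is independently inspectable, and the whole run
#' is reproducible from (config, seed). A failing stage aborts with the
#' stage name; outputs written before the failure are retained.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param seed Optional seed override.
#' @return A `pipeline_summary` list (also written to
#'   `file.path(out_dir, "summary.json")`).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile(),
                         seed = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(seed)) config$sim$seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  sim <- with_stage("simulate", simulate_feature_table(config$sim))
  write_feature_table(sim$table, file.path(out_dir, "simulated"))
  jsonlite::write_json(
    list(
      features = sim$truth$features,
      samples = sim$truth$samples,
      drift_slope = sim$truth$drift_slope
    ),
    file.path(out_dir, "simulated_truth.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )

  qc <- with_stage("qc_cascade", run_qc_cascade(sim$table, config$qc))
  write_feature_table(qc$table, file.path(out_dir, "qc_filtered"))
  write_report(qc$report, file.path(out_dir, "filter_report.json"))

  imputed <- with_stage("knn_impute", knn_impute(qc$table, config$knn_k))

  # branch A: PQN -> glog, for the PCA technical-variability assessment
  pqn <- with_stage(
    "pqn_normalize", pqn_normalize(imputed, config$pqn_reference)
  )
  glog_a <- with_stage(
    "glog_transform", glog_transform(pqn$table, config$glog_lambda)
  )
  write_feature_table(glog_a, file.path(out_dir, "branchA_pqn_glog"))
  pca <- with_stage(
    "pca_scores", pca_scores(glog_a, config$stats$n_pca_components)
  )
  readr::write_tsv(pca$scores, file.path(out_dir, "pca_scores.tsv"),
    progress = FALSE
  )

  # branch B: TPA for fold changes, glog-TPA for the t-tests
  tpa <- with_stage("tpa_normalize", tpa_normalize(imputed, config$tpa_rescale))
  glog_b <- with_stage(
    "glog_transform", glog_transform(tpa, config$glog_lambda)
  )
  write_feature_table(tpa, file.path(out_dir, "branchB_tpa"))

  diffs <- list()
  for (nm in names(config$contrasts)) {
    ct <- config$contrasts[[nm]]
    diffs[[nm]] <- with_stage(
      paste0("differential_", nm),
      run_differential(glog_b, tpa, ct[1], ct[2], config$stats)
    )
    readr::write_tsv(
      tidy(diffs[[nm]]),
      file.path(out_dir, paste0("differential_", nm, ".tsv")),
      progress = FALSE
    )
  }

  comparison <- NULL
  reversion <- NULL
  if (length(diffs) >= 2) {
    disease <- diffs[[1]]
    treatment <- diffs[[2]]
    comparison <- with_stage(
      "compare_contrasts", compare_contrasts(treatment, disease)
    )
    reversion <- with_stage("classify_reversion", classify_reversion(
      comparison$shared,
      stats::setNames(disease$log2_fc, disease$feature_id),
      stats::setNames(treatment$log2_fc, treatment$feature_id)
    ))
    jsonlite::write_json(
      list(
        comparison = unclass(comparison),
        reversion = reversion
      ),
      file.path(out_dir, "contrast_comparison.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }

  hits <- NULL
  if (config$annotate) {
    hits <- with_stage(
      "annotate", match_features(qc$table, ppm_tol = config$ppm_tol)
    )
    hits$ppm_error <- round(hits$ppm_error, 4)
    readr::write_tsv(hits, file.path(out_dir, "annotation_hits.tsv"),
      progress = FALSE
    )
  }

  stage_tbl <- tidy(qc$report)
  summary <- structure(
    list(
      seed = config$sim$seed,
      n_features_simulated = nrow(sim$table$values),
      n_samples_simulated = ncol(sim$table$values),
      filter_stages = stats::setNames(
        as.list(stage_tbl$n_removed), stage_tbl$stage
      ),
      n_features_after_qc = nrow(qc$table$values),
      n_samples_after_qc = ncol(qc$table$values),
      glog_lambda_branch_a = attr(glog_a, "glog_lambda"),
      glog_lambda_branch_b = attr(glog_b, "glog_lambda"),
      pca_explained_variance = pca$explained_variance,
      contrasts = lapply(diffs, function(d) {
        g <- glance(d)
        list(
          contrast = g$contrast, n_significant = g$n_significant,
          n_up = g$n_up, n_down = g$n_down
        )
      }),
      comparison = if (!is.null(comparison)) {
        list(
          n_significant_treatment = comparison$n_significant_a,
          n_significant_disease = comparison$n_significant_b,
          n_unique_treatment = length(comparison$unique_to_a),
          n_shared = length(comparison$shared),
          pct_unique_treatment = comparison$pct_unique_a,
          pct_shared_treatment = comparison$pct_shared_a
        )
      },
      reversion = if (!is.null(reversion)) {
        list(
          n_reverted = sum(reversion$direction == "reverted"),
          n_exacerbated = sum(reversion$direction == "exacerbated"),
          n_mixed = sum(reversion$direction == "mixed")
        )
      },
      n_annotation_hits = if (!is.null(hits)) nrow(hits),
      n_annotated_features = if (!is.null(hits)) {
        length(unique(hits$feature_id))
      },
      out_dir = out_dir
    ),
    class = "pipeline_summary"
  )
  to_write <- summary[setdiff(names(summary), "out_dir")]
  jsonlite::write_json(to_write, file.path(out_dir, "summary.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  summary
}

#' Render a pipeline summary as text
#'
#' Stage-by-stage counts in narrative order: features in, removals per
#' filter, significant features per contrast, unique/shared split and
#' reversion counts. Every printed number is a field of the summary;
#' percentages display rounded to the nearest integer.
#'
#' @param summary A `pipeline_summary` from [run_pipeline()].
#' @return Character vector of lines, invisibly printed by
#'   `print.pipeline_summary`.
#' @export
render_summary <- function(summary) {
  lines <- c(
    sprintf(
      "Simulated %d features x %d injections (seed %d)",
      summary$n_features_simulated, summary$n_samples_simulated, summary$seed
    ),
    vapply(names(summary$filter_stages), function(st) {
      sprintf("  filter %-20s removed %d", st, summary$filter_stages[[st]])
    }, character(1)),
    sprintf(
      "QC-filtered table: %d features x %d samples",
      summary$n_features_after_qc, summary$n_samples_after_qc
    )
  )
  for (nm in names(summary$contrasts)) {
    ct <- summary$contrasts[[nm]]
    lines <- c(lines, sprintf(
      "Contrast %s (%s): %d significant (%d up, %d down)",
      nm, ct$contrast, ct$n_significant, ct$n_up, ct$n_down
    ))
  }
  if (!is.null(summary$comparison)) {
    cmp <- summary$comparison
    pct_u <- if (is.na(cmp$pct_unique_treatment)) "-" else
      sprintf("%d%%", round(cmp$pct_unique_treatment))
    pct_s <- if (is.na(cmp$pct_shared_treatment)) "-" else
      sprintf("%d%%", round(cmp$pct_shared_treatment))
    lines <- c(lines, sprintf(
      "Treatment-significant features: %d unique to treatment (%s), %d shared with disease (%s)",
      cmp$n_unique_treatment, pct_u, cmp$n_shared, pct_s
    ))
  }
  if (!is.null(summary$reversion)) {
    rv <- summary$reversion
    lines <- c(lines, sprintf(
      "Shared features: %d reverted, %d exacerbated, %d mixed",
      rv$n_reverted, rv$n_exacerbated, rv$n_mixed
    ))
  }
  if (!is.null(summary$n_annotation_hits)) {
    lines <- c(lines, sprintf(
      "Annotation: %d putative hits on %d features",
      summary$n_annotation_hits, summary$n_annotated_features
    ))
  }
  lines
}

#' @export
print.pipeline_summary <- function(x, ...) {
  cat(render_summary(x), sep = "\n")
  invisible(x)
}
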