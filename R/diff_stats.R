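#' Statistical configuration for differential calling
#'
#' @param alpha Significance level for the per-feature test (strict
#'   `p < alpha`; default 0.05).
#' @param fc_low,fc_high Fold-change window; a feature must fall strictly
#'   outside `[fc_low, fc_high]` (defaults 0.8 and 1.2) as well as pass the
#'   p-value cut to be called differential.
#' @param test `"welch"` (default; unequal variances are typical of disease
#'   models) or `"student"` (pooled variance).
#' @param p_adjust Multiple-testing adjustment method passed to
#'   [stats::p.adjust()]; `"none"` by default — the conventional raw-p +
#'   fold-change-window rule.
#' @param n_pca_components Components returned by [pca_scores()].
#' @return A `stats_config` list.
#' @export
stats_config <- function(alpha = 0.05, fc_low = 0.8, fc_high = 1.2,
                         test = c("welch", "student"), p_adjust = "none",
                         n_pca_components = 2) {
  test <- match.arg(test)
  stopifnot(alpha > 0, alpha < 1, fc_low < 1, fc_high > 1)
  structure(
    list(
      alpha = alpha, fc_low = fc_low, fc_high = fc_high, test = test,
      p_adjust = p_adjust, n_pca_components = as.integer(n_pca_components)
    ),
    class = "stats_config"
  )
}

#' Principal component scores of a feature table
#'
#' Mean-centres the features (no scaling) and returns per-sample scores and
#' explained-variance fractions — the standard visual check that pooled-QC
#' injections cluster tightly relative to the biological spread.
#'
#' @param mt A fully observed [metab_table()] (branch-A processed:
#'   imputed, PQN-normalized, glog-transformed).
#' @param n_components Number of components to return.
#' @return A `metab_pca` object: `scores` (tibble with `sample_id`, `role`,
#'   `group`, `PC1`, ...) and `explained_variance` (fractions, non-increasing).
#' @export
pca_scores <- function(mt, n_components = 2) {
  x <- mt$values
  if (anyNA(x)) {
    stop("missing values present; run knn_impute() first", call. = FALSE)
  }
  n_components <- min(n_components, nrow(x), ncol(x))
  pc <- stats::prcomp(t(x), center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- tibble::as_tibble(pc$x[, seq_len(n_components), drop = FALSE])
  out <- dplyr::bind_cols(
    dplyr::select(mt$samples,
      sample_id = "id", "role", "group", "injection_order"
    ),
    scores
  )
  structure(
    list(
      scores = out,
      explained_variance = ev[seq_len(n_components)]
    ),
    class = "metab_pca"
  )
}

#' @export
print.metab_pca <- function(x, ...) {
  cat("<metab_pca>", nrow(x$scores), "samples;",
    paste0(
      names(x$scores)[grep("^PC", names(x$scores))], " ",
      sprintf("%.1f%%", 100 * x$explained_variance),
      collapse = ", "
    ), "\n"
  )
  invisible(x)
}

#' @export
tidy.metab_pca <- function(x, ...) x$scores

#' @export
glance.metab_pca <- function(x, ...) {
  tibble::tibble(
    n_components = length(x$explained_variance),
    explained_variance_total = sum(x$explained_variance)
  )
}

#' Two-sample t-test p-value
#'
#' Two-sided Welch (default) or pooled-variance Student t-test. Degenerate
#' inputs never crash: with fewer than two observations per group the
#' p-value is `NA` with a warning; with zero variance in both groups the
#' p-value is 1 when the means are equal and 0 otherwise (the limit of the
#' t statistic).
#'
#' @param a,b Numeric vectors of observations.
#' @param test `"welch"` or `"student"`.
#' @return A p-value in `[0, 1]`, or `NA`.
#' @export
ttest_feature <- function(a, b, test = c("welch", "student")) {
  test <- match.arg(test)
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) {
    warning("fewer than 2 observations per group; returning NA p-value")
    return(NA_real_)
  }
  tryCatch(
    stats::t.test(a, b, var.equal = (test == "student"))$p.value,
    error = function(e) {
      # essentially-constant data: the limit of the t statistic
      if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0
    }
  )
}

#' Fold change between two groups
#'
#' `mean(a) / mean(b)`, computed on total-peak-area-normalized (never
#' glog-transformed) intensities so it estimates a relative concentration
#' ratio.
#'
#' @param a,b Numeric vectors on the TPA scale.
#' @return A positive real.
#' @export
fold_change <- function(a, b) {
  mb <- mean(b, na.rm = TRUE)
  if (!is.finite(mb) || mb <= 0) {
    stop("fold change undefined: mean of denominator group is not positive",
      call. = FALSE
    )
  }
  mean(a, na.rm = TRUE) / mb
}

#' Differential call from p-value and fold change
#'
#' `TRUE` iff `p < alpha` and the fold change lies strictly outside
#' `[fc_low, fc_high]`; boundary values are not significant.
#'
#' @param p P-value.
#' @param fc Fold change.
#' @param config A [stats_config()].
#' @return Logical.
#' @export
call_differential <- function(p, fc, config = stats_config()) {
  !is.na(p) & !is.na(fc) & p < config$alpha &
    (fc < config$fc_low | fc > config$fc_high)
}

#' Per-feature differential analysis for one contrast
#'
#' Runs the univariate pipeline for a two-group contrast: the t-test on the
#' glog-transformed TPA table (`test_table`), the fold change on the
#' untransformed TPA table (`fc_table`), and the joint p-value /
#' fold-change-window call. The two tables must share features and samples.
#'
#' @param test_table A [metab_table()] on the test scale (glog TPA).
#' @param fc_table A [metab_table()] on the fold-change scale (TPA); defaults
#'   to `test_table` (only sensible if that table is untransformed).
#' @param group_a,group_b Biological group names; fold change is A over B.
#' @param config A [stats_config()].
#' @return A `metab_diff` tibble: `feature_id`, `contrast`, `group_a`,
#'   `group_b`, `p_value`, `fold_change`, `log2_fc`, `significant`.
#' @export
run_differential <- function(test_table, fc_table = test_table,
                             group_a, group_b, config = stats_config()) {
  stopifnot(identical(test_table$features$id, fc_table$features$id))
  sa <- test_table$samples$id[
    test_table$samples$role == "biological" &
      test_table$samples$group == group_a
  ]
  sb <- test_table$samples$id[
    test_table$samples$role == "biological" &
      test_table$samples$group == group_b
  ]
  if (!length(sa) || !length(sb)) {
    stop("empty group in contrast ", group_a, " vs ", group_b, call. = FALSE)
  }
  ta <- test_table$values[, sa, drop = FALSE]
  tb <- test_table$values[, sb, drop = FALSE]
  fa <- fc_table$values[, sa, drop = FALSE]
  fb <- fc_table$values[, sb, drop = FALSE]

  p <- vapply(
    seq_len(nrow(ta)),
    function(i) suppressWarnings(ttest_feature(ta[i, ], tb[i, ], config$test)),
    numeric(1)
  )
  if (!identical(config$p_adjust, "none")) {
    p <- stats::p.adjust(p, method = config$p_adjust)
  }
  fc <- vapply(
    seq_len(nrow(fa)),
    function(i) fold_change(fa[i, ], fb[i, ]),
    numeric(1)
  )
  out <- tibble::tibble(
    feature_id = test_table$features$id,
    contrast = paste0(group_a, " vs ", group_b),
    group_a = group_a, group_b = group_b,
    p_value = p,
    fold_change = fc,
    log2_fc = log2(fc),
    significant = call_differential(p, fc, config)
  )
  class(out) <- c("metab_diff", class(out))
  attr(out, "config") <- config
  out
}

#' @export
tidy.metab_diff <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @export
glance.metab_diff <- function(x, ...) {
  cfg <- attr(x, "config")
  tibble::tibble(
    contrast = x$contrast[1],
    n_features = nrow(x),
    n_significant = sum(x$significant, na.rm = TRUE),
    n_up = sum(x$significant & x$fold_change > 1, na.rm = TRUE),
    n_down = sum(x$significant & x$fold_change < 1, na.rm = TRUE),
    alpha = cfg$alpha, fc_low = cfg$fc_low, fc_high = cfg$fc_high
  )
}

#' Partition significant features across two contrasts
#'
#' Splits the union of the two contrasts' significant feature sets into
#' features unique to each contrast and features shared by both, with
#' percentages relative to each contrast's significant set (full precision
#' retained; display rounds to the nearest integer percent).
#'
#' @param a,b `metab_diff` results over the same feature universe.
#' @return A `contrast_classification`: id sets `unique_to_a`, `unique_to_b`,
#'   `shared`; counts; `pct_unique_a` = 100 * |unique_to_a| / |significant in
#'   a|, and the analogous `pct_shared_a`, `pct_unique_b`, `pct_shared_b`.
#' @export
compare_contrasts <- function(a, b) {
  if (anyDuplicated(a$feature_id) || anyDuplicated(b$feature_id)) {
    stop("duplicated feature ids in differential results", call. = FALSE)
  }
  if (!setequal(a$feature_id, b$feature_id)) {
    stop("contrasts cover different feature universes", call. = FALSE)
  }
  sig_a <- a$feature_id[a$significant %in% TRUE]
  sig_b <- b$feature_id[b$significant %in% TRUE]
  shared <- intersect(sig_a, sig_b)
  ua <- setdiff(sig_a, sig_b)
  ub <- setdiff(sig_b, sig_a)
  pct <- function(n, d) if (d > 0) 100 * n / d else NA_real_
  structure(
    list(
      contrast_a = a$contrast[1], contrast_b = b$contrast[1],
      unique_to_a = ua, unique_to_b = ub, shared = shared,
      n_significant_a = length(sig_a), n_significant_b = length(sig_b),
      pct_unique_a = pct(length(ua), length(sig_a)),
      pct_shared_a = pct(length(shared), length(sig_a)),
      pct_unique_b = pct(length(ub), length(sig_b)),
      pct_shared_b = pct(length(shared), length(sig_b))
    ),
    class = "contrast_classification"
  )
}

#' @export
print.contrast_classification <- function(x, ...) {
  cat("<contrast_classification>\n")
  cat(
    "  A:", x$contrast_a, "-", x$n_significant_a, "significant;",
    length(x$unique_to_a), "unique",
    if (x$n_significant_a > 0) sprintf("(%d%%)", round(x$pct_unique_a)), "\n"
  )
  cat(
    "  B:", x$contrast_b, "-", x$n_significant_b, "significant;",
    length(x$unique_to_b), "unique\n"
  )
  cat("  shared:", length(x$shared),
    if (x$n_significant_a > 0) sprintf("(%d%% of A)", round(x$pct_shared_a)),
    "\n"
  )
  invisible(x)
}

#' @export
glance.contrast_classification <- function(x, ...) {
  tibble::tibble(
    contrast_a = x$contrast_a, contrast_b = x$contrast_b,
    n_significant_a = x$n_significant_a,
    n_significant_b = x$n_significant_b,
    n_unique_a = length(x$unique_to_a),
    n_unique_b = length(x$unique_to_b),
    n_shared = length(x$shared),
    pct_unique_a = x$pct_unique_a, pct_shared_a = x$pct_shared_a
  )
}

#' Classify shared differential features as reverted or exacerbated
#'
#' For features significant in both the disease contrast (diabetic vs
#' non-diabetic) and the treatment contrast (treated vs diabetic): the
#' treatment reverts a feature when it moves it against the diabetic shift
#' (the two log2 fold changes have opposite signs), exacerbates it when it
#' pushes in the same direction, and the degenerate zero-effect case is
#' `mixed`.
#'
#' @param shared_ids Feature ids significant in both contrasts.
#' @param disease_log2fc,treatment_log2fc Named numeric vectors (names =
#'   feature ids) of log2 fold changes from each contrast.
#' @return A tibble `feature_id`, `disease_log2fc`, `treatment_log2fc`,
#'   `direction` (`"reverted"`, `"exacerbated"` or `"mixed"`).
#' @export
classify_reversion <- function(shared_ids, disease_log2fc, treatment_log2fc) {
  d <- disease_log2fc[shared_ids]
  t <- treatment_log2fc[shared_ids]
  if (anyNA(d) || anyNA(t)) {
    stop("missing log2 fold change for a shared feature", call. = FALSE)
  }
  prod <- d * t
  tibble::tibble(
    feature_id = as.character(shared_ids),
    disease_log2fc = unname(d),
    treatment_log2fc = unname(t),
    direction = dplyr::case_when(
      prod < 0 ~ "reverted",
      prod > 0 ~ "exacerbated",
      TRUE ~ "mixed"
    )
  )
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test. For combined sample sizes up to 12 the null
#' distribution of U is fully enumerated over all group labelings (exact
#' even under ties, using midranks); larger samples use the normal
#' approximation with tie correction and continuity correction.
#'
#' @param a,b Numeric vectors with at least one observation each.
#' @return A two-sided p-value.
#' @export
mann_whitney <- function(a, b) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  n1 <- length(a)
  n2 <- length(b)
  stopifnot(n1 >= 1, n2 >= 1)
  pooled <- c(a, b)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2

  if (n1 + n2 <= 12) {
    combos <- utils::combn(n1 + n2, n1)
    u_null <- apply(combos, 2, function(idx) {
      sum(r[idx]) - n1 * (n1 + 1) / 2
    })
    eps <- 1e-9
    p_le <- mean(u_null <= u_obs + eps)
    p_ge <- mean(u_null >= u_obs - eps)
    return(min(1, 2 * min(p_le, p_ge)))
  }

  ties <- table(pooled)
  mu <- n1 * n2 / 2
  n <- n1 + n2
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  z <- (u_obs - mu - sign(u_obs - mu) * 0.5) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Relative expression by the delta-delta-Ct method
#'
#' Fold change of a qPCR target in a treated sample relative to a control,
#' each normalized to a reference gene:
#' `2^-((Ct_target,treated - Ct_ref,treated) - (Ct_target,control -
#' Ct_ref,control))`.
#'
#' @param ct_target_treated,ct_ref_treated Ct values in the treated sample.
#' @param ct_target_control,ct_ref_control Ct values in the control sample.
#' @return A positive fold change.
#' @export
ddct_fold_change <- function(ct_target_treated, ct_ref_treated,
                             ct_target_control, ct_ref_control) {
  stopifnot(is.finite(c(
    ct_target_treated, ct_ref_treated, ct_target_control, ct_ref_control
  )))
  ddct <- (ct_target_treated - ct_ref_treated) -
    (ct_target_control - ct_ref_control)
  2^(-ddct)
}
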