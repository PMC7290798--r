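#' k-nearest-neighbour missing value imputation
#'
#' Imputes each missing cell from the `k` most similar features (the
#' microarray-style choice: features that co-vary carry information about
#' each other). For a missing cell (feature f, sample s) the candidate
#' neighbours are the features observed in s; the distance between f and a
#' candidate g is the Euclidean distance over the samples where both are
#' observed, scaled by the number of shared samples
#' (`sqrt(sum((x_f - x_g)^2) / n_shared)`), so features sharing few samples
#' are not unfairly favoured. The imputed value is the inverse-distance
#' weighted mean of the k nearest neighbours' values in s; zero-distance
#' neighbours take all the weight, shared equally. Observed values are never
#' changed.
#'
#' @param mt A [metab_table()] in which every feature has at least one
#'   observed value.
#' @param k Number of neighbours (default 5).
#' @return A `metab_table` with no missing values.
#' @export
knn_impute <- function(mt, k = 5) {
  stopifnot(k >= 1)
  x <- mt$values
  obs <- !is.na(x)
  if (any(rowSums(obs) == 0)) {
    stop("feature with no observed values: '",
      mt$features$id[rowSums(obs) == 0][1],
      "' (filter before imputing)",
      call. = FALSE
    )
  }
  if (all(obs)) return(mt)

  x0 <- x
  x0[!obs] <- 0
  need <- which(rowSums(!obs) > 0)
  for (f in need) {
    xf <- x0[f, ]
    of <- obs[f, ]
    # shared-sample-scaled distance from f to every other feature
    shared <- sweep(obs, 2, of, `&`)
    n_shared <- rowSums(shared)
    diff2 <- sweep(x0, 2, xf, `-`)^2
    diff2[!shared] <- 0
    d <- sqrt(rowSums(diff2) / pmax(n_shared, 1))
    d[n_shared == 0] <- Inf
    d[f] <- Inf

    for (s in which(!of)) {
      cand <- which(obs[, s] & is.finite(d))
      if (!length(cand)) {
        stop("no imputation neighbour for feature '", mt$features$id[f],
          "' in sample '", mt$samples$id[s], "'",
          call. = FALSE
        )
      }
      ord <- cand[order(d[cand], cand)]
      nn <- ord[seq_len(min(k, length(ord)))]
      dn <- d[nn]
      if (any(dn == 0)) {
        w <- as.numeric(dn == 0)
      } else {
        w <- 1 / dn
      }
      x[f, s] <- sum(w * x0[nn, s]) / sum(w)
    }
  }
  set_values(mt, x)
}

#' Probabilistic quotient normalization
#'
#' Corrects per-sample dilution: the reference spectrum is the per-feature
#' median over the reference samples (pooled QCs by default, the batch's
#' technical reference); each sample's dilution factor is the median of its
#' feature-wise quotients against the reference (features with zero
#' reference excluded), and the sample is divided by that factor. Factors
#' are returned for audit; re-running on the output yields factors of 1.
#'
#' @param mt A fully observed [metab_table()] (impute first).
#' @param reference `"qc_median"` (default) or `"all_sample_median"`.
#' @return A list with `table` (normalized `metab_table`) and `factors`
#'   (tibble `sample_id`, `factor`).
#' @export
pqn_normalize <- function(mt, reference = c("qc_median", "all_sample_median")) {
  reference <- match.arg(reference)
  x <- mt$values
  if (anyNA(x)) stop("missing values present; impute first", call. = FALSE)
  ref_cols <- if (reference == "qc_median") {
    mt$samples$role == "qc"
  } else {
    rep(TRUE, ncol(x))
  }
  if (!any(ref_cols)) stop("reference sample set is empty", call. = FALSE)
  r <- apply(x[, ref_cols, drop = FALSE], 1, stats::median)
  use <- r > 0
  if (!any(use)) stop("reference spectrum is all zero", call. = FALSE)
  q <- x[use, , drop = FALSE] / r[use]
  d <- apply(q, 2, stats::median)
  out <- sweep(x, 2, d, `/`)
  list(
    table = set_values(mt, out),
    factors = tibble::tibble(sample_id = mt$samples$id, factor = unname(d))
  )
}

#' Generalized logarithm transform
#'
#' Replaces every intensity x with `ln((x + sqrt(x^2 + lambda^2)) / 2)`:
#' log-like at high intensity, linear-like near zero, variance-stabilizing
#' for data with an additive noise floor under multiplicative noise. At
#' `lambda = 0` it reduces to the natural log (and requires strictly
#' positive data). Strictly increasing in x, so orderings and rank tests
#' are unaffected.
#'
#' @param mt A [metab_table()] (missing values pass through as missing).
#' @param lambda Transform parameter, same units as the intensities; `NULL`
#'   selects it from the pooled QCs via [estimate_glog_lambda()].
#' @return A `metab_table` of transformed values. Transformed intensities
#'   may be negative; the non-negativity invariant applies to raw peak
#'   areas, so the result carries attribute `scale = "glog"`.
#' @export
glog_transform <- function(mt, lambda = NULL) {
  if (is.null(lambda)) lambda <- estimate_glog_lambda(mt)
  stopifnot(lambda >= 0)
  x <- mt$values
  if (lambda == 0 && any(x == 0, na.rm = TRUE)) {
    stop("lambda = 0 requires strictly positive intensities", call. = FALSE)
  }
  g <- glog(x, lambda)
  dimnames(g) <- dimnames(x)
  mt$values <- g
  attr(mt, "scale") <- "glog"
  attr(mt, "glog_lambda") <- lambda
  mt
}

glog <- function(x, lambda) log((x + sqrt(x^2 + lambda^2)) / 2)

#' Select the glog parameter from pooled QCs
#'
#' Chooses `lambda` on a log-spaced grid by minimizing the mean absolute
#' deviation of the per-feature variances of the glog-transformed QC
#' intensities from their grand mean, relative to that grand mean — the
#' variance-stabilization criterion:
#' pooled QCs are technical replicates, so after a good transform every
#' feature should show about the same variance. Deterministic given the
#' table.
#'
#' @param mt A [metab_table()] with at least two QC samples.
#' @param grid Optional numeric vector of candidate lambdas; by default 61
#'   log-spaced values spanning 1e-4 to 1e3 times the median observed QC
#'   intensity.
#' @return The selected lambda (smallest grid value on ties).
#' @export
estimate_glog_lambda <- function(mt, grid = NULL) {
  qc <- mt$values[, mt$samples$role == "qc", drop = FALSE]
  if (ncol(qc) < 2) {
    stop("need >= 2 QC samples to estimate lambda; supply one explicitly",
      call. = FALSE
    )
  }
  if (is.null(grid)) {
    med <- stats::median(qc, na.rm = TRUE)
    if (!is.finite(med) || med <= 0) med <- 1
    grid <- 10^seq(log10(med * 1e-4), log10(med * 1e3), length.out = 61)
  }
  if (length(grid) == 1) return(grid)
  crit <- vapply(grid, function(l) glog_spread(qc, l), numeric(1))
  grid[which.min(crit)]
}

# mean absolute deviation of per-feature glog variances from their grand
# mean, relative to that mean. The relative form matters: large lambda
# shrinks every variance towards zero, so an unnormalized spread would be
# trivially minimized by lambda -> Inf rather than by stabilization.
glog_spread <- function(qc, lambda) {
  g <- glog(qc, lambda)
  v <- apply(g, 1, stats::var, na.rm = TRUE)
  v <- v[is.finite(v)]
  if (!length(v) || mean(v) <= 0) return(Inf)
  mean(abs(v - mean(v))) / mean(v)
}

#' Total-peak-area normalization
#'
#' Divides each sample by its total peak area so every sample has the same
#' total. With `rescale = "median_total"` (default) the result is
#' multiplied by the median of the original sample totals, keeping
#' magnitudes on the familiar peak-area scale; `"unit_sum"` leaves each
#' column summing to exactly 1.
#'
#' @param mt A fully observed [metab_table()].
#' @param rescale `"median_total"` or `"unit_sum"`.
#' @return A `metab_table`.
#' @export
tpa_normalize <- function(mt, rescale = c("median_total", "unit_sum")) {
  rescale <- match.arg(rescale)
  x <- mt$values
  if (anyNA(x)) stop("missing values present; impute first", call. = FALSE)
  totals <- colSums(x)
  if (any(totals <= 0)) {
    stop("sample with non-positive total peak area: '",
      mt$samples$id[totals <= 0][1], "'",
      call. = FALSE
    )
  }
  out <- sweep(x, 2, totals, `/`)
  if (rescale == "median_total") out <- out * stats::median(totals)
  set_values(mt, out)
}
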