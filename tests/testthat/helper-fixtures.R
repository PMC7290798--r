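# Build a small metab_table from a matrix and per-sample roles.
# Biological samples are assigned to `groups` cyclically unless given.
make_table <- function(values, roles, groups = NULL, assay = "HILIC",
                       polarity = "positive") {
  nf <- nrow(values)
  ns <- ncol(values)
  fid <- if (is.null(rownames(values))) paste0("F", seq_len(nf)) else
    rownames(values)
  sid <- if (is.null(colnames(values))) paste0("S", seq_len(ns)) else
    colnames(values)
  dimnames(values) <- list(fid, sid)
  if (is.null(groups)) {
    groups <- rep(NA_character_, ns)
    bio <- which(roles == "biological")
    groups[bio] <- rep(c("A", "B"), length.out = length(bio))
  }
  metab_table(
    values = values,
    features = tibble::tibble(
      id = fid, mz = 100 + seq_len(nf), rt = 60 + 10 * seq_len(nf),
      polarity = polarity, assay = assay
    ),
    samples = tibble::tibble(
      id = sid, role = roles, group = groups, injection_order = seq_len(ns)
    )
  )
}

# Toy cascade fixture: 6 features, 15 QCs (5 equilibration), 20 biological,
# 2 blanks; exactly one feature violates each feature-level filter rule.
make_cascade_toy <- function() {
  n_qc <- 15
  n_bio <- 20
  n_blank <- 2
  ns <- n_qc + n_bio + n_blank
  roles <- c(rep("qc", n_qc), rep("biological", n_bio), rep("blank", n_blank))
  v <- matrix(100, 6, ns)
  rownames(v) <- c(
    "good1", "fail_blank", "fail_rsd", "fail_qcdet", "fail_overall", "good2"
  )
  blank_cols <- which(roles == "blank")
  qc_post <- which(roles == "qc")[-(1:5)] # QCs surviving equilibration removal
  bio_cols <- which(roles == "biological")

  v[, blank_cols] <- 1 # blanks detect everything faintly
  v["fail_blank", blank_cols] <- 100 # QC mean 100 < 20 x 100
  v["fail_rsd", qc_post] <- rep(c(50, 150), 5) # RSD ~52% > 30%
  v["fail_qcdet", qc_post[1:2]] <- NA # 8/10 QC detection < 90%
  # overall detection: 10 QC + 3 bio + 2 blank = 15/32 < 50%
  v["fail_overall", bio_cols[4:20]] <- NA
  make_table(v, roles)
}

# Welch / pooled t-test p-value from the textbook formulas (test oracle).
oracle_ttest <- function(a, b, pooled = FALSE) {
  na <- length(a)
  nb <- length(b)
  va <- var(a)
  vb <- var(b)
  if (pooled) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  } else {
    se2 <- va / na + vb / nb
    t <- (mean(a) - mean(b)) / sqrt(se2)
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  2 * stats::pt(-abs(t), df)
}

# Exact two-sided rank-sum p by full enumeration of group labelings
# (independent of the package's implementation).
oracle_mann_whitney <- function(a, b) {
  n1 <- length(a)
  n <- n1 + length(b)
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u_all <- apply(utils::combn(n, n1), 2, function(idx) {
    sum(r[idx]) - n1 * (n1 + 1) / 2
  })
  eps <- 1e-9
  min(1, 2 * min(mean(u_all <= u_obs + eps), mean(u_all >= u_obs - eps)))
}
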