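#' Create a feature table
#'
#' A `metab_table` bundles a features x samples peak-area matrix with feature
#' metadata (m/z, retention time, polarity, assay) and sample metadata (role,
#' biological group, injection order). It is the object every pipeline stage
#' consumes and returns, so stages chain with the pipe. Missing peak areas are
#' stored as `NA`, never as zero, so "not detected" stays distinguishable from
#' "detected at zero area".
#'
#' @param values Numeric matrix of non-negative peak areas, features in rows
#'   and samples in columns; `NA` marks a missing (undetected) value. Row and
#'   column names must match the metadata ids.
#' @param features Data frame of feature metadata with columns `id`, `mz`
#'   (Thomson), `rt` (seconds), `polarity` (`"positive"` or `"negative"`) and
#'   `assay` (`"HILIC"` or `"LIPIDS"`).
#' @param samples Data frame of sample metadata with columns `id`, `role`
#'   (`"biological"`, `"qc"` or `"blank"`), `group` (`NA` unless biological)
#'   and `injection_order` (unique positive integers).
#'
#' @return An object of class `metab_table`.
#' @export
#' @examples
#' mt <- metab_table(
#'   values = matrix(c(10, 20, 30, 40), 2, 2,
#'     dimnames = list(c("F1", "F2"), c("QC1", "S1"))
#'   ),
#'   features = data.frame(
#'     id = c("F1", "F2"), mz = c(181.07, 520.34), rt = c(65, 310),
#'     polarity = "positive", assay = "HILIC"
#'   ),
#'   samples = data.frame(
#'     id = c("QC1", "S1"), role = c("qc", "biological"),
#'     group = c(NA, "ND-V"), injection_order = 1:2
#'   )
#' )
#' mt
metab_table <- function(values, features, samples) {
  features <- tibble::as_tibble(features)
  samples <- tibble::as_tibble(samples)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  mt <- structure(
    list(values = values, features = features, samples = samples),
    class = "metab_table"
  )
  validate_metab_table(mt)
}

validate_metab_table <- function(mt) {
  values <- mt$values
  features <- mt$features
  samples <- mt$samples

  need_f <- c("id", "mz", "rt", "polarity", "assay")
  miss <- setdiff(need_f, names(features))
  if (length(miss)) {
    stop("feature metadata lacks column(s): ", paste(miss, collapse = ", "),
      call. = FALSE
    )
  }
  need_s <- c("id", "role", "group", "injection_order")
  miss <- setdiff(need_s, names(samples))
  if (length(miss)) {
    stop("sample metadata lacks column(s): ", paste(miss, collapse = ", "),
      call. = FALSE
    )
  }
  if (anyDuplicated(features$id)) {
    stop("duplicated feature id: ", features$id[duplicated(features$id)][1],
      call. = FALSE
    )
  }
  if (anyDuplicated(samples$id)) {
    stop("duplicated sample id: ", samples$id[duplicated(samples$id)][1],
      call. = FALSE
    )
  }
  if (nrow(values) != nrow(features) ||
    !identical(rownames(values), as.character(features$id))) {
    bad <- setdiff(rownames(values), features$id)
    if (!length(bad)) bad <- setdiff(features$id, rownames(values))
    stop(
      "matrix rows do not match feature metadata",
      if (length(bad)) paste0(" (first offender: '", bad[1], "')"),
      call. = FALSE
    )
  }
  if (ncol(values) != nrow(samples) ||
    !identical(colnames(values), as.character(samples$id))) {
    bad <- c(
      setdiff(colnames(values), samples$id),
      setdiff(samples$id, colnames(values))
    )
    stop(
      "matrix columns do not match sample metadata",
      if (length(bad)) {
        paste0(" (offending id(s): '", paste(bad, collapse = "', '"), "')")
      },
      call. = FALSE
    )
  }
  if (any(values < 0, na.rm = TRUE)) {
    idx <- which(values < 0, arr.ind = TRUE)[1, ]
    stop("negative intensity at feature '", rownames(values)[idx[1]],
      "', sample '", colnames(values)[idx[2]], "'",
      call. = FALSE
    )
  }
  bad_role <- setdiff(unique(samples$role), c("biological", "qc", "blank"))
  if (length(bad_role)) {
    stop("unknown sample role: '", bad_role[1], "'", call. = FALSE)
  }
  grp <- samples$group
  nonbio <- samples$role != "biological"
  if (any(nonbio & !is.na(grp) & grp != "")) {
    stop("qc/blank sample carries a biological group: '",
      samples$id[nonbio & !is.na(grp) & grp != ""][1], "'",
      call. = FALSE
    )
  }
  if (any(!nonbio & (is.na(grp) | grp == ""))) {
    stop("biological sample lacks a group: '",
      samples$id[!nonbio & (is.na(grp) | grp == "")][1],
      "'",
      call. = FALSE
    )
  }
  io <- samples$injection_order
  if (any(is.na(io)) || any(io <= 0) || any(io != as.integer(io))) {
    stop("injection_order must be positive integers", call. = FALSE)
  }
  if (anyDuplicated(io)) {
    stop("injection_order values must be unique", call. = FALSE)
  }
  mt
}

#' @export
print.metab_table <- function(x, ...) {
  roles <- table(factor(x$samples$role, c("biological", "qc", "blank")))
  n_na <- sum(is.na(x$values))
  cat(
    "<metab_table> ", nrow(x$values), " features x ", ncol(x$values),
    " samples (", roles[["biological"]], " biological, ", roles[["qc"]],
    " QC, ", roles[["blank"]], " blank)\n",
    sep = ""
  )
  cat(sprintf(
    "  missing: %d cells (%.1f%%)\n", n_na,
    100 * n_na / max(1, length(x$values))
  ))
  invisible(x)
}

#' Subset a feature table
#'
#' Row/column subsetting keeps the matrix and both metadata tables aligned.
#' Indices may be ids, logical vectors or integer positions.
#'
#' @param x A [metab_table()].
#' @param i Feature selection (ids, logical or positions); missing keeps all.
#' @param j Sample selection; missing keeps all.
#' @param ... Unused.
#' @return A `metab_table`.
#' @export
`[.metab_table` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$values))
  if (missing(j)) j <- seq_len(ncol(x$values))
  if (is.character(i)) i <- match(i, x$features$id)
  if (is.character(j)) j <- match(j, x$samples$id)
  if (anyNA(i)) stop("unknown feature id in subset", call. = FALSE)
  if (anyNA(j)) stop("unknown sample id in subset", call. = FALSE)
  metab_table(
    values = x$values[i, j, drop = FALSE],
    features = x$features[i, , drop = FALSE],
    samples = x$samples[j, , drop = FALSE]
  )
}

#' Accessors for the parts of a feature table
#'
#' @param mt A [metab_table()].
#' @param role Optional sample role filter for `sample_ids()`.
#' @return `intensity_matrix()` the numeric matrix; `feature_info()` and
#'   `sample_info()` the metadata tibbles; `sample_ids()` a character vector.
#' @export
intensity_matrix <- function(mt) mt$values

#' @rdname intensity_matrix
#' @export
feature_info <- function(mt) mt$features

#' @rdname intensity_matrix
#' @export
sample_info <- function(mt) mt$samples

#' @rdname intensity_matrix
#' @export
sample_ids <- function(mt, role = NULL) {
  s <- mt$samples
  if (!is.null(role)) s <- s[s$role %in% role, , drop = FALSE]
  as.character(s$id)
}

#' Long-format view of a feature table
#'
#' @param x A [metab_table()].
#' @param ... Unused.
#' @return A tibble with one row per (feature, sample) cell: `feature_id`,
#'   `sample_id`, `intensity` plus the sample role/group columns.
#' @export
as_tibble.metab_table <- function(x, ...) {
  long <- tibble::tibble(
    feature_id = rep(rownames(x$values), times = ncol(x$values)),
    sample_id = rep(colnames(x$values), each = nrow(x$values)),
    intensity = as.vector(x$values)
  )
  dplyr::left_join(
    long,
    dplyr::select(x$samples, sample_id = "id", "role", "group"),
    by = "sample_id"
  )
}

# Replace the matrix, preserving metadata; internal.
set_values <- function(mt, values) {
  stopifnot(identical(dim(values), dim(mt$values)))
  dimnames(values) <- dimnames(mt$values)
  mt$values <- values
  validate_metab_table(mt)
}
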