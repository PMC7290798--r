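#' Read a feature table from TSV files
#'
#' Reads the three standard text files of an untargeted LC-MS export: the
#' peak-area matrix (first column feature id, one column per sample), a
#' feature-metadata table (`id`, `mz`, `rt`, `polarity`, `assay`) and a
#' sample-metadata table (`id`, `role`, `group`, `injection_order`). Empty
#' cells and the `na` sentinel parse to missing; literal zeros are mapped to
#' missing when `zero_is_missing = TRUE` (the default), since peak-picking
#' exports use both conventions for "not detected".
#'
#' @param matrix_path Path to the peak-area matrix TSV.
#' @param feature_meta_path Path to the feature metadata TSV.
#' @param sample_meta_path Path to the sample metadata TSV.
#' @param na Character sentinel(s) parsed as missing (default `"NA"`).
#' @param zero_is_missing Map literal zero intensities to missing on ingest.
#' @param rt_unit Unit of the `rt` column in the feature metadata; `"minutes"`
#'   is converted to seconds on load. Retention times are stored in seconds.
#' @return A [metab_table()].
#' @export
read_feature_table <- function(matrix_path, feature_meta_path,
                               sample_meta_path, na = "NA",
                               zero_is_missing = TRUE,
                               rt_unit = c("seconds", "minutes")) {
  rt_unit <- match.arg(rt_unit)
  mat_df <- readr::read_tsv(matrix_path,
    na = c(na, ""), col_types = readr::cols(),
    show_col_types = FALSE, progress = FALSE
  )
  features <- readr::read_tsv(feature_meta_path,
    col_types = readr::cols(), show_col_types = FALSE, progress = FALSE
  )
  samples <- readr::read_tsv(sample_meta_path,
    col_types = readr::cols(), show_col_types = FALSE, progress = FALSE
  )

  fid <- as.character(mat_df[[1]])
  sid <- names(mat_df)[-1]
  bad <- setdiff(fid, features$id)
  if (length(bad)) {
    stop("matrix feature '", bad[1], "' absent from feature metadata",
      call. = FALSE
    )
  }
  bad <- setdiff(features$id, fid)
  if (length(bad)) {
    stop("feature metadata id '", bad[1], "' absent from matrix",
      call. = FALSE
    )
  }
  bad <- setdiff(sid, samples$id)
  if (length(bad)) {
    stop("matrix column '", bad[1], "' absent from sample metadata",
      call. = FALSE
    )
  }
  bad <- setdiff(samples$id, sid)
  if (length(bad)) {
    stop("sample metadata id '", bad[1], "' absent from matrix",
      call. = FALSE
    )
  }

  values <- as.matrix(mat_df[, -1, drop = FALSE])
  if (!is.numeric(values)) {
    stop("non-numeric intensity values in matrix", call. = FALSE)
  }
  rownames(values) <- fid
  if (zero_is_missing) values[!is.na(values) & values == 0] <- NA_real_

  features <- features[match(fid, features$id), , drop = FALSE]
  samples <- samples[match(sid, samples$id), , drop = FALSE]
  if (rt_unit == "minutes") features$rt <- features$rt * 60
  if (is.character(samples$group)) {
    samples$group[samples$group == ""] <- NA_character_
  }
  metab_table(values, features, samples)
}

#' Write a feature table to TSV files
#'
#' Inverse of [read_feature_table()]: writes `<prefix>_matrix.tsv`,
#' `<prefix>_features.tsv` and `<prefix>_samples.tsv`. Missing values are
#' written as `NA`.
#'
#' @param mt A [metab_table()].
#' @param prefix Path prefix for the three files.
#' @return Invisibly, the three paths written.
#' @export
write_feature_table <- function(mt, prefix) {
  paths <- paste0(prefix, c("_matrix.tsv", "_features.tsv", "_samples.tsv"))
  mat_df <- tibble::as_tibble(mt$values, rownames = "feature_id")
  readr::write_tsv(mat_df, paths[1], na = "NA", progress = FALSE)
  readr::write_tsv(mt$features, paths[2], na = "NA", progress = FALSE)
  readr::write_tsv(mt$samples, paths[3], na = "NA", progress = FALSE)
  invisible(paths)
}

new_filter_report <- function(n_features_in, n_samples_in) {
  structure(
    list(
      stages = tibble::tibble(
        stage = character(), axis = character(),
        removed = list(), params = list()
      ),
      n_features_in = as.integer(n_features_in),
      n_samples_in = as.integer(n_samples_in)
    ),
    class = "filter_report"
  )
}

add_stage <- function(report, stage, axis, removed, params) {
  prior <- unlist(report$stages$removed[report$stages$axis == axis])
  if (length(intersect(prior, removed))) {
    stop("id removed twice on the same axis: '",
      intersect(prior, removed)[1], "'",
      call. = FALSE
    )
  }
  report$stages <- dplyr::bind_rows(
    report$stages,
    tibble::tibble(
      stage = stage, axis = axis,
      removed = list(as.character(removed)), params = list(params)
    )
  )
  report
}

report_counts <- function(report, axis) {
  n_in <- if (axis == "feature") report$n_features_in else report$n_samples_in
  removed <- sum(lengths(report$stages$removed[report$stages$axis == axis]))
  c(n_input = n_in, n_removed = removed, n_output = n_in - removed)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("<filter_report>", nrow(x$stages), "stage(s)\n")
  for (axis in c("feature", "sample")) {
    ct <- report_counts(x, axis)
    cat(sprintf(
      "  %ss: %d in, %d removed, %d out\n", axis,
      ct["n_input"], ct["n_removed"], ct["n_output"]
    ))
  }
  if (nrow(x$stages)) {
    for (k in seq_len(nrow(x$stages))) {
      cat(sprintf(
        "  %2d. %-24s [%s] removed %d\n", k, x$stages$stage[k],
        x$stages$axis[k], length(x$stages$removed[[k]])
      ))
    }
  }
  invisible(x)
}

#' @export
tidy.filter_report <- function(x, ...) {
  tibble::tibble(
    stage = x$stages$stage,
    axis = x$stages$axis,
    n_removed = lengths(x$stages$removed),
    removed = x$stages$removed,
    params = x$stages$params
  )
}

#' @export
glance.filter_report <- function(x, ...) {
  f <- report_counts(x, "feature")
  s <- report_counts(x, "sample")
  tibble::tibble(
    n_stages = nrow(x$stages),
    n_features_in = f[["n_input"]], n_features_out = f[["n_output"]],
    n_samples_in = s[["n_input"]], n_samples_out = s[["n_output"]]
  )
}

#' Write or read a filter report
#'
#' Serializes the per-stage provenance of a QC filter cascade (stage name,
#' axis, removed ids, parameter values, input/output counts) as JSON. The
#' write/read pair round-trips losslessly.
#'
#' @param report A `filter_report` as produced by [run_qc_cascade()].
#' @param path File path.
#' @return `write_report()` returns `path` invisibly; `read_report()` a
#'   `filter_report`.
#' @export
write_report <- function(report, path) {
  stages <- purrr::pmap(report$stages, function(stage, axis, removed, params) {
    list(
      stage = stage, axis = axis,
      n_removed = length(removed), removed = as.list(removed),
      params = params
    )
  })
  out <- list(
    stages = stages,
    features = as.list(report_counts(report, "feature")),
    samples = as.list(report_counts(report, "sample"))
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  raw <- jsonlite::read_json(path)
  rep <- new_filter_report(raw$features$n_input, raw$samples$n_input)
  for (st in raw$stages) {
    rep <- add_stage(
      rep, st$stage, st$axis,
      as.character(unlist(st$removed)),
      lapply(st$params, identity)
    )
  }
  rep
}
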