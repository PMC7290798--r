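Package: metaboflow
Title: QC Filtering, Normalization and Differential Analysis for Untargeted LC-MS Feature Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for untargeted UHPLC-MS peak-area
    feature tables with pooled-QC, blank and biological injections. Implements
    the standard quality-assurance cascade (equilibration-QC removal, blank
    ratio filtering, sample missingness, pooled-QC relative standard deviation
    and detection-rate filters), k-nearest-neighbour missing value imputation,
    probabilistic quotient and total-peak-area normalization, generalized-log
    transformation, per-feature univariate differential testing with
    fold-change windows, multi-contrast set classification (unique, shared,
    reverted, exacerbated), and simplified putative adduct annotation by
    ppm-tolerance mass matching. Ships a seeded synthetic run-sequence and
    feature-table generator with planted ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
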