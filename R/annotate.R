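PROTON_MASS <- 1.00727646688
ELECTRON_MASS <- 0.00054857990946

# monoisotopic element masses (Da)
ELEMENT_MASS <- c(
  C = 12.0, H = 1.00782503207, N = 14.0030740048, O = 15.9949146196,
  P = 30.97376163, S = 31.97207100, Na = 22.9897692809,
  Cl = 34.96885268, K = 38.96370668, F = 18.99840322
)

#' Monoisotopic mass of an elemental formula
#'
#' Parses a plain elemental formula (e.g. `"C6H12O6"`; supported elements
#' C, H, N, O, P, S, Na, Cl, K, F) and returns its monoisotopic mass.
#'
#' @param formula Character vector of formulas.
#' @return Numeric vector of masses in Da.
#' @export
#' @examples
#' formula_mass("C6H12O6") # glucose, 180.06339
formula_mass <- function(formula) {
  vapply(formula, function(f) {
    m <- gregexpr("([A-Z][a-z]?)([0-9]*)", f)[[1]]
    parts <- regmatches(f, list(m))[[1]]
    if (!length(parts) || paste(parts, collapse = "") != f) {
      stop("cannot parse formula '", f, "'", call. = FALSE)
    }
    total <- 0
    for (p in parts) {
      el <- gsub("[0-9]", "", p)
      n <- gsub("[A-Za-z]", "", p)
      n <- if (n == "") 1L else as.integer(n)
      if (!el %in% names(ELEMENT_MASS)) {
        stop("unknown element '", el, "' in formula '", f, "'", call. = FALSE)
      }
      total <- total + ELEMENT_MASS[[el]] * n
    }
    total
  }, numeric(1), USE.NAMES = FALSE)
}

#' Default adduct rules
#'
#' The minimal electrospray adduct set: protonated, sodiated and ammoniated
#' ions in positive mode; deprotonated and formate in negative mode. Mass
#' shifts include the electron. User-extensible via [read_adduct_list()].
#'
#' @return A tibble `name`, `mass_shift` (Da), `charge` (+1/-1), `polarity`.
#' @export
default_adducts <- function() {
  tibble::tibble(
    name = c(
      "[M+H]+", "[M+Na]+", "[M+NH4]+", "[M-H]-", "[M+HCOO]-"
    ),
    mass_shift = c(
      PROTON_MASS,
      ELEMENT_MASS[["Na"]] - ELECTRON_MASS,
      ELEMENT_MASS[["N"]] + 4 * ELEMENT_MASS[["H"]] - ELECTRON_MASS,
      -PROTON_MASS,
      ELEMENT_MASS[["C"]] + ELEMENT_MASS[["H"]] +
        2 * ELEMENT_MASS[["O"]] + ELECTRON_MASS
    ),
    charge = c(1L, 1L, 1L, -1L, -1L),
    polarity = c("positive", "positive", "positive", "negative", "negative")
  )
}

validate_adducts <- function(adducts) {
  stopifnot(all(c("name", "mass_shift", "charge", "polarity") %in%
    names(adducts)))
  if (any(abs(adducts$charge) != 1)) {
    stop("only singly charged adducts are supported", call. = FALSE)
  }
  ok <- (adducts$charge > 0) == (adducts$polarity == "positive")
  if (!all(ok)) {
    stop("adduct charge sign does not match polarity: '",
      adducts$name[!ok][1], "'",
      call. = FALSE
    )
  }
  adducts
}

#' Read adduct rules or a compound list from TSV
#'
#' `read_adduct_list()` expects columns `name`, `mass_shift`, `charge`,
#' `polarity`; `read_compound_list()` expects `name`, `formula`,
#' `monoisotopic_mass` and checks each stated mass against the formula
#' within 1e-4 Da. The bundled demonstration compound list (a testing aid
#' spanning common cardiac metabolite classes, not a curated resource) is
#' at `system.file("extdata", "compounds_demo.tsv", package = "metaboflow")`.
#'
#' @param path TSV path.
#' @return A tibble.
#' @export
read_adduct_list <- function(path) {
  validate_adducts(readr::read_tsv(path,
    col_types = readr::cols(), show_col_types = FALSE, progress = FALSE
  ))
}

#' @rdname read_adduct_list
#' @export
read_compound_list <- function(path) {
  cmp <- readr::read_tsv(path,
    col_types = readr::cols(), show_col_types = FALSE, progress = FALSE
  )
  stopifnot(all(c("name", "formula", "monoisotopic_mass") %in% names(cmp)))
  calc <- formula_mass(cmp$formula)
  off <- abs(calc - cmp$monoisotopic_mass) > 1e-4
  if (any(off)) {
    stop("stated monoisotopic mass inconsistent with formula for '",
      cmp$name[off][1], "' (stated ", cmp$monoisotopic_mass[off][1],
      ", computed ", round(calc[off][1], 5), ")",
      call. = FALSE
    )
  }
  if (any(cmp$monoisotopic_mass <= 0)) {
    stop("non-positive monoisotopic mass", call. = FALSE)
  }
  cmp
}

bundled_compounds <- function() {
  read_compound_list(
    system.file("extdata", "compounds_demo.tsv", package = "metaboflow")
  )
}

#' Adduct m/z from a neutral mass
#'
#' `m/z = (neutral_mass + mass_shift) / |charge|`.
#'
#' @param neutral_mass Monoisotopic neutral mass (Da), positive.
#' @param mass_shift Signed adduct mass shift (Da).
#' @param charge Signed integer charge (+/-1).
#' @return m/z in Thomson.
#' @export
adduct_mz <- function(neutral_mass, mass_shift, charge = 1L) {
  stopifnot(all(neutral_mass > 0), all(abs(charge) >= 1))
  mz <- (neutral_mass + mass_shift) / abs(charge)
  if (any(mz <= 0)) stop("adduct m/z is not positive", call. = FALSE)
  mz
}

#' Parts-per-million mass error
#'
#' `1e6 * (observed - theoretical) / theoretical`.
#'
#' @param observed_mz,theoretical_mz m/z values (Th); theoretical positive.
#' @return Signed ppm error.
#' @export
ppm_error <- function(observed_mz, theoretical_mz) {
  stopifnot(all(theoretical_mz > 0))
  1e6 * (observed_mz - theoretical_mz) / theoretical_mz
}

#' Group co-eluting features by retention time
#'
#' Single-linkage grouping: two features link when their retention times
#' differ by at most `window` seconds, and groups are the connected
#' components (so a chain of features each within the window of the next
#' forms one group). Invariant to input order.
#'
#' @param features A data frame with columns `id` and `rt` (seconds).
#' @param window Linkage window in seconds (default 2).
#' @return The input tibble with an integer `rt_group` column; group numbers
#'   follow elution order.
#' @export
group_features_by_rt <- function(features, window = 2) {
  stopifnot(window > 0)
  features <- tibble::as_tibble(features)
  if (!nrow(features)) {
    return(dplyr::mutate(features, rt_group = integer(0)))
  }
  ord <- order(features$rt, features$id)
  rt_sorted <- features$rt[ord]
  new_group <- c(TRUE, diff(rt_sorted) > window)
  grp_sorted <- cumsum(new_group)
  grp <- integer(nrow(features))
  grp[ord] <- grp_sorted
  dplyr::mutate(features, rt_group = grp)
}

#' Putative annotation by accurate-mass matching
#'
#' A simplified putative annotation step: every (compound, adduct) pair
#' whose polarity matches a feature and whose theoretical m/z lies within
#' the assay's ppm tolerance of the observed m/z is emitted as a hit.
#' Multiple hits per feature (isomers, multiple ion forms) are expected and
#' never collapsed. Tolerances default to 12 ppm for HILIC and 14 ppm for
#' LIPIDS; the boundary is inclusive (`|ppm| <= tol`). Hits are putative
#' annotations — Metabolomics Standards Initiative level 2.
#'
#' @param mt A [metab_table()].
#' @param compounds Compound tibble (`name`, `monoisotopic_mass`); default
#'   the bundled demonstration list.
#' @param adducts Adduct tibble; default [default_adducts()].
#' @param ppm_tol Named vector of ppm tolerances per assay.
#' @return A tibble of hits: `feature_id`, `compound`, `adduct`,
#'   `theoretical_mz`, `observed_mz`, `ppm_error`, `msi_level` (2).
#' @export
match_features <- function(mt, compounds = bundled_compounds(),
                           adducts = default_adducts(),
                           ppm_tol = c(HILIC = 12, LIPIDS = 14)) {
  stopifnot(nrow(compounds) > 0, nrow(adducts) > 0, all(ppm_tol >= 0))
  adducts <- validate_adducts(adducts)
  # all theoretical (compound, adduct) m/z values
  theo <- tidyr::crossing(
    dplyr::select(compounds, compound = "name", "monoisotopic_mass"),
    dplyr::select(adducts,
      adduct = "name", "mass_shift", "charge",
      adduct_polarity = "polarity"
    )
  )
  theo$theoretical_mz <- adduct_mz(
    theo$monoisotopic_mass, theo$mass_shift, theo$charge
  )

  feats <- mt$features
  hits <- purrr::map_dfr(seq_len(nrow(feats)), function(i) {
    tol <- ppm_tol[[feats$assay[i]]]
    if (is.null(tol)) {
      stop("no ppm tolerance configured for assay '", feats$assay[i], "'",
        call. = FALSE
      )
    }
    cand <- theo[theo$adduct_polarity == feats$polarity[i], , drop = FALSE]
    err <- ppm_error(feats$mz[i], cand$theoretical_mz)
    sel <- abs(err) <= tol
    if (!any(sel)) return(NULL)
    tibble::tibble(
      feature_id = feats$id[i],
      compound = cand$compound[sel],
      adduct = cand$adduct[sel],
      theoretical_mz = cand$theoretical_mz[sel],
      observed_mz = feats$mz[i],
      ppm_error = err[sel],
      msi_level = 2L
    )
  })
  if (!nrow(hits)) {
    hits <- tibble::tibble(
      feature_id = character(), compound = character(), adduct = character(),
      theoretical_mz = numeric(), observed_mz = numeric(),
      ppm_error = numeric(), msi_level = integer()
    )
  }
  hits
}

# (compound, adduct) targets whose m/z falls inside the assay's acquisition
# range; used by the simulator's plant_annotatable option and by recovery
# tests.
annotatable_targets <- function(assay, compounds = bundled_compounds(),
                                adducts = default_adducts()) {
  rng <- assay_mz_range(assay)
  theo <- tidyr::crossing(
    dplyr::select(compounds, compound = "name", "monoisotopic_mass"),
    dplyr::select(adducts,
      adduct = "name", "mass_shift", "charge", "polarity"
    )
  )
  theo$mz <- adduct_mz(theo$monoisotopic_mass, theo$mass_shift, theo$charge)
  theo <- theo[theo$mz >= rng[1] & theo$mz <= rng[2], , drop = FALSE]
  theo[order(theo$compound, theo$adduct), , drop = FALSE]
}

plant_adduct_features <- function(nf, assay) {
  targets <- annotatable_targets(assay)
  k <- min(nf, nrow(targets), 20L)
  targets[seq_len(k), c("mz", "polarity", "compound", "adduct"), drop = FALSE]
}
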