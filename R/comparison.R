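# Pairing the two phenometric streams, sanity checks against field-guide
# onset dates, and CI-width-vs-effort analyses.

#' Match survey and incidental phenometrics into paired units
#'
#' Inner join on (species, cell, year, percentile): a unit enters the
#' comparison only when a phenometric was estimable from both streams.
#' Unmatched rows on either side are counted in a message; duplicate keys
#' within one stream are an error.
#'
#' @param survey_phen,incidental_phen phenometric tibbles from
#'   [survey_phenometrics()] and [incidental_phenometrics()].
#' @return tibble of paired units with `_survey`/`_incidental` suffixed
#'   estimate, CI and effort columns, plus `delta_doy` (incidental minus
#'   survey) and `ci_overlap` (closed-interval intersection).
#' @export
match_paired_units <- function(survey_phen, incidental_phen) {
  keys <- c("species_id", "cell_id", "year", "percentile")
  if (nrow(incidental_phen) == 0 || nrow(survey_phen) == 0) {
    warning("one stream has no phenometrics; paired table is empty")
    return(tibble::tibble())
  }
  for (nm in c("survey", "incidental")) {
    tab <- if (nm == "survey") survey_phen else incidental_phen
    assert_columns(tab, keys, paste0(nm, " phenometrics"))
    if (anyDuplicated(tab[, keys]) > 0) {
      stop("duplicate unit keys in the ", nm, " stream", call. = FALSE)
    }
  }
  pairs <- dplyr::inner_join(survey_phen, incidental_phen, by = keys,
                             suffix = c("_survey", "_incidental"))
  message(sprintf(
    "paired %d unit-percentiles (%d survey-only, %d incidental-only dropped)",
    nrow(pairs), nrow(survey_phen) - nrow(pairs),
    nrow(incidental_phen) - nrow(pairs)))
  if (nrow(pairs) == 0) return(pairs)
  pairs$delta_doy <- pairs$doy_estimate_incidental - pairs$doy_estimate_survey
  pairs$ci_overlap <- pairs$ci_low_survey <= pairs$ci_high_incidental &
    pairs$ci_low_incidental <= pairs$ci_high_survey
  pairs
}

#' Lag of early-season estimates behind the day-0 reference
#'
#' Day 0 is one week before the typical flight-initiation date taken from
#' regional field guides; a 10%-DOY estimate falling before day 0 flags a
#' likely estimation artifact. `day0_lag` returns per-unit lags; units whose
#' species lacks a reference are skipped with a message.
#'
#' @param phenometrics a phenometric tibble (any stream), percentile-10 rows
#'   are used.
#' @param day0_refs tibble `species_id`, `guide_onset_doy` (optionally a
#'   `region` column matched against one in `phenometrics`).
#' @return `phenometrics` rows with `day0` and `lag_days` columns
#'   (`lag_days = doy_estimate - day0`).
#' @export
day0_lag <- function(phenometrics, day0_refs) {
  assert_columns(day0_refs, c("species_id", "guide_onset_doy"), "day0_refs")
  p10 <- phenometrics[phenometrics$percentile == 10, , drop = FALSE]
  by <- "species_id"
  if ("region" %in% names(day0_refs) && "region" %in% names(p10)) {
    by <- c("species_id", "region")
  }
  out <- dplyr::inner_join(p10, day0_refs, by = by)
  skipped <- nrow(p10) - nrow(out)
  if (skipped > 0) {
    message(sprintf("%d unit(s) skipped: no day-0 reference", skipped))
  }
  out$day0 <- out$guide_onset_doy - 7
  out$lag_days <- out$doy_estimate - out$day0
  out
}

#' Proportion of early-season estimates falling before day 0, per stream
#'
#' @inheritParams day0_lag
#' @return tibble: `source`, `n_units`, `n_before_day0`, `prop_before_day0`.
#' @export
summarize_day0 <- function(phenometrics, day0_refs) {
  lagged <- day0_lag(phenometrics, day0_refs)
  lagged |>
    dplyr::group_by(.data$source) |>
    dplyr::summarise(n_units = dplyr::n(),
                     n_before_day0 = sum(.data$lag_days < 0),
                     prop_before_day0 = mean(.data$lag_days < 0),
                     .groups = "drop")
}

#' Confidence-interval overlap between streams
#'
#' Overlap uses closed intervals (touching endpoints count). A species'
#' incidental estimates are "persistently earlier" when they precede the
#' survey estimate in every matched 10%-percentile unit, with at least
#' `min_units` such units.
#'
#' @param pairs paired tibble from [match_paired_units()].
#' @param min_units minimum matched units for the persistently-earlier call.
#' @return list: `overall` (tibble per percentile: n_pairs, overlap_rate),
#'   `by_species` (per species x percentile), `persistently_earlier`
#'   (character vector of species ids).
#' @export
ci_overlap_summary <- function(pairs, min_units = 3) {
  stopifnot(nrow(pairs) >= 1)
  overall <- pairs |>
    dplyr::group_by(.data$percentile) |>
    dplyr::summarise(n_pairs = dplyr::n(),
                     overlap_rate = mean(.data$ci_overlap, na.rm = TRUE),
                     .groups = "drop")
  by_species <- pairs |>
    dplyr::group_by(.data$species_id, .data$percentile) |>
    dplyr::summarise(n_pairs = dplyr::n(),
                     overlap_rate = mean(.data$ci_overlap, na.rm = TRUE),
                     n_incidental_earlier = sum(.data$delta_doy < 0),
                     .groups = "drop")
  pe <- by_species |>
    dplyr::filter(.data$percentile == 10, .data$n_pairs >= min_units,
                  .data$n_incidental_earlier == .data$n_pairs)
  list(overall = overall, by_species = by_species,
       persistently_earlier = pe$species_id)
}

#' Regress CI width on sampling effort and confusability
#'
#' Per stream and percentile, a linear model of bootstrap CI width on the
#' stream's effort covariates (surveys and sites for the survey stream,
#' record count for the incidental stream) plus species confusability.
#'
#' @param phenometrics one stream's phenometric tibble.
#' @param traits species trait tibble with `confusability`.
#' @return tibble of coefficients: `source`, `percentile`, `term`,
#'   `estimate`, `se`, `p_value`, `n`. A constant CI width draws a
#'   degenerate-fit warning and `NA` slopes.
#' @export
ci_width_regression <- function(phenometrics, traits) {
  dat <- dplyr::inner_join(
    phenometrics, traits[, c("species_id", "confusability")],
    by = "species_id")
  dat <- dat[!is.na(dat$ci_width), , drop = FALSE]
  src <- dat$source[1]
  rhs <- if (identical(src, "survey")) {
    c("n_surveys", "n_sites", "confusability")
  } else {
    c("n_records", "confusability")
  }
  purrr::map(split(dat, dat$percentile), function(d) {
    p <- d$percentile[1]
    if (sd(d$ci_width) == 0) {
      warning(sprintf("constant CI width (%s, p%g): degenerate fit", src, p))
      return(tibble::tibble(source = src, percentile = p,
                            term = rhs, estimate = 0, se = NA_real_,
                            p_value = NA_real_, n = nrow(d)))
    }
    keep <- rhs[vapply(rhs, function(v) sd(d[[v]]) > 0, TRUE)]
    fit <- lm(stats::reformulate(keep, "ci_width"), data = d)
    cm <- summary(fit)$coefficients
    tibble::tibble(source = src, percentile = p, term = rownames(cm),
                   estimate = cm[, 1], se = cm[, 2], p_value = cm[, 4],
                   n = nrow(d))
  }) |> dplyr::bind_rows()
}
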