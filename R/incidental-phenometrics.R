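# Percentile phenometrics from presence-only occurrence records: dedup,
# unit filtering, empirical quantiles, and record-resampling bootstrap CIs.

#' Remove cross-platform duplicate occurrence records
#'
#' Records are duplicates if they share species, date, longitude and latitude
#' (coordinates compared at full stored precision); exactly one record per
#' key is retained (the first in input order). Idempotent.
#'
#' @param records occurrence tibble with `species_id`, `date`, `lon`, `lat`
#'   (and typically `platform`).
#' @return deduplicated tibble.
#' @export
deduplicate_occurrences <- function(records) {
  assert_columns(records, c("species_id", "date", "lon", "lat"), "records")
  dplyr::distinct(records, .data$species_id, .data$date, .data$lon,
                  .data$lat, .keep_all = TRUE)
}

#' Select incidental units with enough records
#'
#' A (species, cell, year) unit is eligible iff it has at least `min_records`
#' deduplicated records; no other density rule applies.
#'
#' @param records deduplicated occurrence tibble; `cell_id` is derived from
#'   lon/lat when absent, `year` from the date.
#' @param min_records record threshold.
#' @return tibble: `species_id`, `cell_id`, `year`, `n_records`.
#' @export
filter_incidental_units <- function(records, min_records = 10) {
  assert_columns(records, c("species_id", "date", "lon", "lat"), "records")
  records <- dplyr::mutate(records, date = as.Date(.data$date))
  if (!"cell_id" %in% names(records)) {
    records$cell_id <- cell_id_from_lonlat(records$lon, records$lat)
  }
  records |>
    dplyr::mutate(year = year_of(.data$date)) |>
    dplyr::group_by(.data$species_id, .data$cell_id, .data$year) |>
    dplyr::summarise(n_records = dplyr::n(), .groups = "drop") |>
    dplyr::filter(.data$n_records >= min_records) |>
    dplyr::arrange(.data$species_id, .data$cell_id, .data$year)
}

#' Empirical quantile of record days-of-year
#'
#' Linear interpolation of order statistics (the standard type-7 convention),
#' so the estimate is continuous in the sample; the convention is exposed via
#' `type` for sensitivity checks. Monotone in `p` and equivariant under
#' shifting all days by a constant.
#'
#' @param doys numeric vector of record days-of-year (>= 1 value).
#' @param p percentile in \[0, 100\].
#' @param type quantile type passed to [stats::quantile()].
#' @return real day-of-year.
#' @export
quantile_doy <- function(doys, p, type = 7) {
  if (length(doys) == 0 || all(is.na(doys))) {
    stop("no days-of-year supplied", call. = FALSE)
  }
  quantile(doys, probs = p / 100, type = type, names = FALSE, na.rm = TRUE)
}

#' Bootstrap phenometric for one incidental unit
#'
#' Resamples the unit's record days-of-year with replacement `B` times and
#' recomputes the quantile; the CI is the percentile interval of the
#' bootstrap distribution, the point estimate comes from the full data.
#'
#' @param doys record days-of-year for one unit.
#' @param p percentiles to extract (vector).
#' @param B bootstrap replicates (>= 2).
#' @param seed integer seed.
#' @param level confidence level.
#' @param type quantile convention (see [quantile_doy()]).
#' @param keys optional named list (`species_id`, `cell_id`, `year`) carried
#'   into the output.
#' @return tibble with one row per percentile: keys, `source`
#'   (`"incidental"`), `percentile`, `doy_estimate`, `ci_low`, `ci_high`,
#'   `ci_width`, `n_records`.
#' @export
bootstrap_incidental_phenometric <- function(doys, p = c(10, 50), B = 500,
                                             seed = 1, level = 0.95,
                                             type = 7, keys = NULL) {
  stopifnot(B >= 2)
  est <- vapply(p, function(pp) quantile_doy(doys, pp, type), 0)
  n <- length(doys)
  set.seed(seed)
  boot <- matrix(NA_real_, B, length(p))
  for (b in seq_len(B)) {
    res <- doys[sample.int(n, n, replace = TRUE)]
    boot[b, ] <- vapply(p, function(pp) quantile_doy(res, pp, type), 0)
  }
  alpha <- (1 - level) / 2
  ci <- apply(boot, 2, quantile, probs = c(alpha, 1 - alpha), names = FALSE)
  tibble::tibble(
    species_id = keys$species_id %||% NA_character_,
    cell_id = keys$cell_id %||% NA_character_,
    year = keys$year %||% NA_integer_,
    source = "incidental", percentile = as.numeric(p),
    doy_estimate = est, ci_low = ci[1, ], ci_high = ci[2, ],
    ci_width = ci[2, ] - ci[1, ], n_records = n)
}

#' Incidental-stream phenometrics for every eligible unit
#'
#' Deduplicates, derives cells and years, filters units by record count, then
#' computes bootstrap phenometrics per unit. The full pipeline is invariant
#' to input row order (records are sorted on the dedup keys internally).
#'
#' @param records occurrence tibble (`species_id`, `date`, `lon`, `lat`,
#'   `platform`).
#' @param percentiles percentiles to extract.
#' @param B,level,type bootstrap and quantile settings.
#' @param seed integer seed; per-unit seeds derived from it.
#' @param min_records eligibility threshold.
#' @return tibble of phenometrics (one row per unit x percentile).
#' @export
incidental_phenometrics <- function(records, percentiles = c(10, 50),
                                    B = 500, seed = 1, level = 0.95,
                                    type = 7, min_records = 10) {
  records <- dplyr::mutate(records, date = as.Date(.data$date)) |>
    dplyr::arrange(.data$species_id, .data$date, .data$lon, .data$lat)
  records <- deduplicate_occurrences(records)
  if (!"cell_id" %in% names(records)) {
    records$cell_id <- cell_id_from_lonlat(records$lon, records$lat)
  }
  records <- dplyr::mutate(records, year = year_of(.data$date),
                           doy = doy_of(.data$date))
  units <- filter_incidental_units(records, min_records)
  if (nrow(units) == 0) {
    message("no incidental units pass the record threshold")
    return(tibble::tibble())
  }
  purrr::map(seq_len(nrow(units)), function(i) {
    u <- units[i, ]
    d <- records$doy[records$species_id == u$species_id &
                       records$cell_id == u$cell_id &
                       records$year == u$year]
    bootstrap_incidental_phenometric(
      d, p = percentiles, B = B, seed = seed + i, level = level, type = type,
      keys = list(species_id = u$species_id, cell_id = u$cell_id,
                  year = u$year))
  }) |> dplyr::bind_rows()
}
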