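#' Daily growing degree days by the single-sine method
#'
#' Computes one day's growing degree days (GDD, degree-days Celsius) from the
#' daily minimum and maximum temperature by integrating a sine curve passed
#' through `tmin` and `tmax`, truncated below at the base threshold and capped
#' horizontally at the upper threshold (Baskerville-Emin-style cutoff). This is
#' the standard single-sine accumulation used for insect development, with the
#' generic butterfly thresholds of 10 and 30 degrees C as defaults.
#'
#' The value equals the daily mean of `max(0, min(T(t), upper) - base)` where
#' `T(t)` runs through one sine cycle between `tmin` and `tmax`; it is bounded
#' in `[0, upper - base]` and non-decreasing in both temperatures.
#'
#' @param tmin,tmax daily minimum and maximum temperature (degrees C);
#'   vectors are recycled to common length. Rows with `tmin > tmax` are
#'   rejected.
#' @param base base (lower development) threshold, degrees C.
#' @param upper upper development threshold, degrees C; must exceed `base`.
#' @return numeric vector of daily degree-days (degree C day).
#' @examples
#' daily_gdd_single_sine(20, 20)          # constant 20 C day -> 10
#' daily_gdd_single_sine(5, 15)           # half-cycle above base -> 5/pi
#' @export
daily_gdd_single_sine <- function(tmin, tmax, base = 10, upper = 30) {
  if (!is.numeric(base) || !is.numeric(upper) || length(base) != 1 ||
      length(upper) != 1 || base >= upper) {
    stop("`base` must be a single number strictly below `upper`", call. = FALSE)
  }
  n <- max(length(tmin), length(tmax))
  tmin <- rep_len(as.numeric(tmin), n)
  tmax <- rep_len(as.numeric(tmax), n)
  bad <- which(tmin > tmax)
  if (length(bad) > 0) {
    stop(sprintf("tmin > tmax in %d row(s) (first at index %d)",
                 length(bad), bad[1]), call. = FALSE)
  }

  m <- (tmax + tmin) / 2   # daily mean
  a <- (tmax - tmin) / 2   # half-amplitude

  dd <- numeric(n)

  below <- tmax <= base
  above <- tmin >= upper
  inside <- !below & !above & tmin >= base & tmax <= upper
  dd[below] <- 0
  dd[above] <- upper - base
  dd[inside] <- m[inside] - base

  # crosses the base threshold only
  cb <- !below & !above & !inside & tmin < base & tmax <= upper
  if (any(cb)) {
    t1 <- asin(pmin(1, pmax(-1, (base - m[cb]) / a[cb])))
    dd[cb] <- ((m[cb] - base) * (pi / 2 - t1) + a[cb] * cos(t1)) / pi
  }

  # crosses the upper threshold only
  cu <- !below & !above & !inside & tmin >= base & tmax > upper
  if (any(cu)) {
    t2 <- asin(pmin(1, pmax(-1, (upper - m[cu]) / a[cu])))
    dd[cu] <- ((m[cu] - base) * (t2 + pi / 2) - a[cu] * cos(t2) +
                 (upper - base) * (pi / 2 - t2)) / pi
  }

  # crosses both thresholds
  cc <- !below & !above & !inside & tmin < base & tmax > upper
  if (any(cc)) {
    t1 <- asin(pmin(1, pmax(-1, (base - m[cc]) / a[cc])))
    t2 <- asin(pmin(1, pmax(-1, (upper - m[cc]) / a[cc])))
    dd[cc] <- ((m[cc] - base) * (t2 - t1) + a[cc] * (cos(t1) - cos(t2)) +
                 (upper - base) * (pi / 2 - t2)) / pi
  }

  pmin(pmax(dd, 0), upper - base)
}

#' Accumulate growing degree days over a seasonal window
#'
#' Sums [daily_gdd_single_sine()] over a fixed day-of-year window for one grid
#' cell and year. The pipeline default window is Jan 1 to Jun 30 (DOY 1-181,
#' or 1-182 in leap years), indexing the thermal energy available before and
#' during early flight periods.
#'
#' @param daily_climate tibble with columns `cell_id`, `date`, `tmin`, `tmax`
#'   (one row per cell-day; if several sub-cell series share a cell-day,
#'   tmin/tmax are averaged across them before the sine computation).
#' @param cell_id,year the cell-year to accumulate.
#' @param window length-2 integer DOY window (inclusive); `NULL` means
#'   Jan 1 - Jun 30 of that calendar year.
#' @param base,upper thresholds passed to [daily_gdd_single_sine()].
#' @return one-row tibble: `cell_id`, `year`, `gdd`, `window_start`,
#'   `window_end`. Errors listing the gaps if any window day is missing.
#' @export
accumulate_gdd <- function(daily_climate, cell_id, year, window = NULL,
                           base = 10, upper = 30) {
  assert_columns(daily_climate, c("cell_id", "date", "tmin", "tmax"),
                 "daily_climate")
  if (is.null(window)) {
    jun30 <- doy_of(as.Date(sprintf("%d-06-30", year)))
    window <- c(1L, jun30)
  }
  dat <- daily_climate[daily_climate$cell_id == cell_id, , drop = FALSE]
  dat$date <- as.Date(dat$date)
  dat <- dat[year_of(dat$date) == year, , drop = FALSE]
  dat$doy <- doy_of(dat$date)
  dat <- dat[dat$doy >= window[1] & dat$doy <= window[2], , drop = FALSE]

  need <- seq.int(window[1], window[2])
  have <- sort(unique(dat$doy))
  gaps <- setdiff(need, have)
  if (length(gaps) > 0) {
    stop(sprintf("climate for cell %s year %d is missing %d day(s) in window (first gaps: %s)",
                 cell_id, year, length(gaps),
                 paste(head(gaps, 5), collapse = ", ")), call. = FALSE)
  }
  # average sub-cell series to a cell-mean tmin/tmax before the sine
  daily <- dat |>
    dplyr::group_by(.data$doy) |>
    dplyr::summarise(tmin = mean(.data$tmin), tmax = mean(.data$tmax),
                     .groups = "drop")
  gdd <- sum(daily_gdd_single_sine(daily$tmin, daily$tmax,
                                   base = base, upper = upper))
  tibble::tibble(cell_id = cell_id, year = as.integer(year), gdd = gdd,
                 window_start = as.integer(window[1]),
                 window_end = as.integer(window[2]))
}

#' GDD table for every cell-year in a climate table
#'
#' @inheritParams accumulate_gdd
#' @return tibble with one row per cell-year (`cell_id`, `year`, `gdd`, window
#'   columns).
#' @export
gdd_table <- function(daily_climate, window = NULL, base = 10, upper = 30) {
  assert_columns(daily_climate, c("cell_id", "date", "tmin", "tmax"),
                 "daily_climate")
  keys <- daily_climate |>
    dplyr::mutate(year = year_of(.data$date)) |>
    dplyr::distinct(.data$cell_id, .data$year)
  purrr::pmap(keys, function(cell_id, year) {
    accumulate_gdd(daily_climate, cell_id, year, window = window,
                   base = base, upper = upper)
  }) |>
    dplyr::bind_rows()
}
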