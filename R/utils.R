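#' @importFrom rlang %||% .data
#' @importFrom stats quantile rnorm rpois runif rbinom rlnorm qnorm dnorm pnorm
#'   uniroot var setNames aggregate as.formula logLik AIC coef predict sd
#'   approx rmultinom lm vcov nobs resid
#' @importFrom utils head tail
#' @importFrom mgcv s
NULL

#' Grid-cell identifier for decimal-degree coordinates
#'
#' One-degree tiles: a record at (lon, lat) belongs to the cell whose
#' south-west corner is `(floor(lon), floor(lat))` — the spatial grain at
#' which both data streams are aggregated.
#'
#' @param lon,lat decimal degrees.
#' @return character ids of the form `c<lon>_<lat>`.
#' @export
cell_id_from_lonlat <- function(lon, lat) {
  sprintf("c%d_%d", floor(lon), floor(lat))
}

#' Day of year (1-based) for a Date vector
#'
#' Jan 1 is DOY 1. Used consistently across all modules.
#'
#' @param date a `Date` vector.
#' @return integer day-of-year.
#' @export
doy_of <- function(date) {
  as.integer(format(as.Date(date), "%j"))
}

year_of <- function(date) {
  as.integer(format(as.Date(date), "%Y"))
}

date_from_doy <- function(year, doy) {
  as.Date(sprintf("%d-01-01", year)) + (doy - 1)
}

days_in_year <- function(year) {
  ifelse((year %% 4 == 0 & year %% 100 != 0) | year %% 400 == 0, 366L, 365L)
}

is_weekend <- function(date) {
  format(as.Date(date), "%u") %in% c("6", "7")
}

assert_columns <- function(df, cols, what = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}
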