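#' Daily time series container
#'
#' A `daily_series` is a thin wrapper around a data frame with a contiguous
#' civil-calendar `date` column and a numeric `value` column.  Counts must be
#' non-negative integers; temperatures may carry `NA` for missing days.
#'
#' @param dates `Date` vector, strictly increasing, one entry per calendar day.
#' @param values numeric vector, same length as `dates`.
#' @param type `"count"` or `"temperature"`.  Counts are validated as
#'   non-negative integers with no missing values; temperatures must be
#'   finite where not missing.
#' @return An object of class `daily_series`: a data frame with columns
#'   `date` and `value`, plus a `type` attribute.
#' @export
daily_series <- function(dates, values, type = c("temperature", "count")) {
  type <- match.arg(type)
  if (!inherits(dates, "Date")) dates <- as.Date(dates)
  if (anyNA(dates)) stop("dates contain unparseable entries")
  if (length(dates) != length(values)) stop("dates and values differ in length")
  if (length(dates) == 0L) stop("empty series")
  d <- as.integer(dates)
  if (length(d) > 1L && any(diff(d) != 1L)) {
    bad <- which(diff(d) != 1L)[1L]
    stop(sprintf("dates must be contiguous calendar days; gap or duplicate after %s",
                 format(dates[bad])))
  }
  values <- as.numeric(values)
  if (type == "count") {
    if (anyNA(values)) stop("count series must not contain missing values")
    if (any(values < 0) || any(values != floor(values)))
      stop("counts must be non-negative integers")
  } else {
    if (any(!is.finite(values) & !is.na(values)))
      stop("temperature values must be finite or NA")
  }
  out <- data.frame(date = dates, value = values)
  class(out) <- c("daily_series", "data.frame")
  attr(out, "type") <- type
  out
}

#' @export
print.daily_series <- function(x, ...) {
  cat(sprintf("<daily_series: %s, %d days, %s .. %s>\n",
              attr(x, "type"), nrow(x), format(x$date[1L]),
              format(x$date[nrow(x)])))
  invisible(x)
}

is_daily_series <- function(x) inherits(x, "daily_series")

stopifnot_daily <- function(x, what = "series") {
  if (!is_daily_series(x)) stop(sprintf("%s must be a daily_series", what))
  invisible(x)
}

check_aligned <- function(a, b) {
  if (nrow(a) != nrow(b) || any(a$date != b$date))
    stop("series calendars are not aligned")
  invisible(TRUE)
}

#' Stable day-of-year index (1..366)
#'
#' Maps each date to an index that is stable across leap and non-leap years:
#' Feb 29 is always index 60 and Mar 1 is always index 61, so "the same day
#' of the year" lines up across years.  In non-leap years index 60 is never
#' produced.
#'
#' @param dates `Date` vector.
#' @return integer vector in 1..366.
#' @export
doy_index <- function(dates) {
  yd <- as.POSIXlt(dates)$yday + 1L     # 1-based ordinal day
  yr <- as.POSIXlt(dates)$year + 1900L
  leap <- (yr %% 4L == 0L & yr %% 100L != 0L) | (yr %% 400L == 0L)
  yd + as.integer(!leap & yd >= 60L)
}

#' Build a contiguous daily calendar spanning whole civil years
#'
#' @param start_year first civil year (January 1).
#' @param n_years number of whole years.
#' @return `Date` vector.
#' @export
year_calendar <- function(start_year, n_years) {
  if (n_years < 1L) stop("n_years must be >= 1")
  seq(as.Date(sprintf("%d-01-01", start_year)),
      as.Date(sprintf("%d-12-31", start_year + n_years - 1L)),
      by = "day")
}

# number of whole years spanned by a contiguous daily calendar (approximate,
# used only for preconditions)
n_years_spanned <- function(dates) {
  as.numeric(dates[length(dates)] - dates[1L] + 1L) / 365.25
}
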