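#' Day-of-year climatology
#'
#' Computes, for each of the 366 stable day-of-year indices (see
#' [doy_index()]), the mean of all observations falling on that day across
#' years.  With `smooth_halfwidth > 0`, observations within that many
#' day-of-year positions (wrapping across the year end) are pooled before
#' averaging; Feb 29 otherwise uses leap-year observations only.
#'
#' @param series a `daily_series` spanning at least two full years.
#' @param smooth_halfwidth non-negative integer pooling half-width in
#'   day-of-year space (default 0 = no pooling).
#' @return list of class `climatology`: `doy_means` (length 366, `NA` where
#'   no observation contributes), `counts_per_doy`, `type`,
#'   `smooth_halfwidth`.
#' @export
build_climatology <- function(series, smooth_halfwidth = 0L) {
  stopifnot_daily(series)
  if (smooth_halfwidth < 0 || smooth_halfwidth != floor(smooth_halfwidth))
    stop("smooth_halfwidth must be a non-negative integer")
  if (nrow(series) < 730L)
    stop("climatology requires at least 2 full years of data")
  doy <- doy_index(series$date)
  ok <- !is.na(series$value)
  sums <- counts <- numeric(366)
  s <- tapply(series$value[ok], doy[ok], sum)
  n <- tapply(series$value[ok], doy[ok], length)
  idx <- as.integer(names(s))
  sums[idx] <- s
  counts[idx] <- n
  h <- as.integer(smooth_halfwidth)
  if (h > 0L) {
    pooled_s <- pooled_n <- numeric(366)
    for (d in 1:366) {
      win <- ((d - h - 1L):(d + h - 1L)) %% 366L + 1L
      pooled_s[d] <- sum(sums[win])
      pooled_n[d] <- sum(counts[win])
    }
    sums <- pooled_s
    counts <- pooled_n
  }
  means <- ifelse(counts > 0, sums / counts, NA_real_)
  structure(list(doy_means = means, counts_per_doy = counts,
                 type = attr(series, "type"), smooth_halfwidth = h),
            class = "climatology")
}

#' Daily anomalies relative to a climatology
#'
#' `anomaly(t) = value(t) - doy_means[doy(t)]`; missing values propagate.
#'
#' @param series a `daily_series`.
#' @param clim a [build_climatology()] result for a compatible variable.
#' @return `daily_series`-like data frame of class `anomaly_series` with
#'   columns `date` and `value` (the anomaly, same units as the input).
#' @export
compute_anomalies <- function(series, clim) {
  stopifnot_daily(series)
  if (!inherits(clim, "climatology")) stop("clim must be a climatology")
  anom <- series$value - clim$doy_means[doy_index(series$date)]
  out <- data.frame(date = series$date, value = anom)
  class(out) <- c("anomaly_series", "data.frame")
  attr(out, "type") <- attr(series, "type")
  out
}

#' Trailing seven-day aggregates of daily anomalies
#'
#' For each day `t`, aggregates the anomalies over the trailing window
#' `t-6 .. t` (inclusive): the sum for counts, the mean for temperatures.
#' The first six days, and any day whose window contains a missing anomaly,
#' are `NA`.  Windows are daily-stepped and overlapping, so there is one
#' value per eligible calendar day.
#'
#' @param anoms an `anomaly_series` (or any data frame with contiguous
#'   `date` and numeric `value`).
#' @param stat `"sum"` or `"mean"`.
#' @param width window length in days (default 7).
#' @return data frame of class `weekly_anomaly` with `date` (window
#'   end-day) and `value`; `stat` stored as an attribute.
#' @export
weekly_aggregate <- function(anoms, stat = c("sum", "mean"), width = 7L) {
  stat <- match.arg(stat)
  if (nrow(anoms) < width) stop(sprintf("need at least %d days of data", width))
  v <- anoms$value
  n <- length(v)
  cs <- cumsum(ifelse(is.na(v), 0, v))
  bad <- cumsum(is.na(v))
  out <- rep(NA_real_, n)
  i <- width:n
  win_sum <- cs[i] - c(0, cs)[i - width + 1L]
  win_bad <- bad[i] - c(0, bad)[i - width + 1L]
  win_sum[win_bad > 0] <- NA_real_
  out[i] <- if (stat == "sum") win_sum else win_sum / width
  res <- data.frame(date = anoms$date, value = out)
  class(res) <- c("weekly_anomaly", "data.frame")
  attr(res, "stat") <- stat
  attr(res, "width") <- as.integer(width)
  res
}
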