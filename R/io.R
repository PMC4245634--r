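# Daily CSV format: header `date,tmax,tmin,count`, ISO-8601 dates, one
# dialect (comma, dot decimal, UTF-8, LF).

#' Read a daily series bundle from CSV
#'
#' Enforces a contiguous calendar.  Calendar gaps become missing
#' temperatures; gap counts become 0 only when `absence_zero = TRUE`
#' (absence of a record meaning "no event that day" must be an explicit
#' choice), otherwise gaps are an error.  Duplicate or non-monotone dates
#' are rejected with the offending line number.
#'
#' @param path CSV file with header `date,tmax,tmin,count`.
#' @param absence_zero treat missing calendar days as zero-count days with
#'   missing temperatures.
#' @return list with `daily_series` elements `tmax`, `tmin`, `count`.
#' @export
read_daily_csv <- function(path, absence_zero = FALSE) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("date", "tmax", "tmin", "count")
  if (!identical(names(raw), need))
    stop(sprintf("header must be exactly '%s'", paste(need, collapse = ",")))
  dates <- as.Date(raw$date, format = "%Y-%m-%d")
  if (anyNA(dates)) {
    bad <- which(is.na(dates))[1L]
    stop(sprintf("line %d: unparseable date '%s'", bad + 1L, raw$date[bad]))
  }
  if (any(duplicated(dates))) {
    bad <- which(duplicated(dates))[1L]
    stop(sprintf("line %d: duplicated date %s", bad + 1L, format(dates[bad])))
  }
  if (is.unsorted(dates)) {
    bad <- which(diff(as.integer(dates)) < 0)[1L] + 1L
    stop(sprintf("line %d: dates not increasing at %s", bad + 1L,
                 format(dates[bad])))
  }
  for (col in c("tmax", "tmin", "count")) {
    v <- raw[[col]]
    bad <- which(!is.na(raw$date) & is.na(suppressWarnings(as.numeric(v))) &
                   !(is.na(v) | v == "" | v == "NA"))
    if (length(bad))
      stop(sprintf("line %d: unparseable %s value '%s'", bad[1L] + 1L, col,
                   v[bad[1L]]))
  }
  full <- seq(dates[1L], dates[length(dates)], by = "day")
  if (length(full) != length(dates)) {
    if (!absence_zero)
      stop(sprintf("calendar has %d missing days; pass absence_zero = TRUE to fill counts with 0",
                   length(full) - length(dates)))
    idx <- match(full, dates)
    raw <- raw[idx, ]
    raw$count[is.na(idx)] <- 0
    dates <- full
  }
  list(tmax = daily_series(dates, as.numeric(raw$tmax), "temperature"),
       tmin = daily_series(dates, as.numeric(raw$tmin), "temperature"),
       count = daily_series(dates, as.numeric(raw$count), "count"))
}

#' Write a daily series bundle to CSV
#'
#' @param bundle list with aligned `tmax`, `tmin`, `count` daily series
#'   (such as from [simulate_daily()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_daily_csv <- function(bundle, path) {
  check_aligned(bundle$tmax, bundle$tmin)
  check_aligned(bundle$tmax, bundle$count)
  fmt <- function(x) ifelse(is.na(x), "NA", sprintf("%.17g", x))
  df <- data.frame(date = format(bundle$tmax$date, "%Y-%m-%d"),
                   tmax = fmt(bundle$tmax$value),
                   tmin = fmt(bundle$tmin$value),
                   count = as.integer(bundle$count$value))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, eol = "\n",
                   fileEncoding = "UTF-8")
  invisible(path)
}
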