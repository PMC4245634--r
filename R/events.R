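# Percentile-based event classification and contingency analysis for weekly
# anomalies.  Quantiles use the linear-interpolation convention (stats type 7)
# throughout; class boundaries are inclusive (>= high cut, <= low cut).

round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Classify high-end and low-end count weeks
#'
#' Thresholds are the stated percentiles (type-7 quantiles) of all eligible
#' weekly values; a day is `high` when its weekly anomaly is at or above the
#' upper cut and `low` when at or below the lower cut.  If the two cuts
#' coincide (degenerate all-equal input) every day is labelled `normal`.
#'
#' @param weekly a [weekly_aggregate()] result for count anomalies.
#' @param low_q,high_q percentiles in (0, 100); defaults 5 and 95.
#' @return list with `labels` (factor `high`/`normal`/`low`, `NA` on
#'   ineligible days, aligned to `weekly$date`) and `thresholds`
#'   (`low_cut`, `high_cut`).
#' @export
classify_suicide_weeks <- function(weekly, low_q = 5, high_q = 95) {
  v <- weekly$value
  ok <- !is.na(v)
  if (!any(ok)) stop("no eligible weekly values")
  if (sum(ok) < 40L)
    stop("need at least 40 eligible days for meaningful percentiles")
  if (low_q >= high_q) stop("low_q must be below high_q")
  cuts <- stats::quantile(v[ok], c(low_q, high_q) / 100, type = 7, names = FALSE)
  low_cut <- cuts[1L]
  high_cut <- cuts[2L]
  lab <- rep(NA_character_, length(v))
  if (high_cut > low_cut) {
    lab[ok] <- ifelse(v[ok] >= high_cut, "high",
                      ifelse(v[ok] <= low_cut, "low", "normal"))
  } else {
    lab[ok] <- "normal"      # degenerate: inclusive rule would double-label
  }
  list(labels = factor(lab, levels = c("high", "normal", "low")),
       thresholds = c(low_cut = low_cut, high_cut = high_cut))
}

#' Monthly profile of weekly temperature anomalies by event class
#'
#' For each calendar month (of the window end-day) and each class
#' (`high`, `low`, `other`), the mean weekly temperature anomaly.  Cells
#' with no contributing days are `NA`.
#'
#' @param weekly_temp a [weekly_aggregate()] result for a temperature.
#' @param labels factor from [classify_suicide_weeks()], aligned by day.
#' @return 12 x 3 numeric matrix (rows Jan..Dec; columns `high`, `low`,
#'   `other`).
#' @export
monthly_event_profile <- function(weekly_temp, labels) {
  if (nrow(weekly_temp) != length(labels))
    stop("labels and weekly_temp must cover the same days")
  mo <- as.POSIXlt(weekly_temp$date)$mon + 1L
  cls <- as.character(labels)
  cls[cls == "normal"] <- "other"
  out <- matrix(NA_real_, 12L, 3L,
                dimnames = list(month.abb, c("high", "low", "other")))
  ok <- !is.na(weekly_temp$value) & !is.na(cls)
  for (m in 1:12) {
    for (cl in colnames(out)) {
      sel <- ok & mo == m & cls == cl
      if (any(sel)) out[m, cl] <- mean(weekly_temp$value[sel])
    }
  }
  out
}

#' Select the months separating high-end and low-end weeks most strongly
#'
#' Ranks months by `|mean(high) - mean(low)|` from a
#' [monthly_event_profile()]; months with an empty high or low cell are
#' excluded from ranking.  An explicit `months` list overrides the ranking
#' (the package default for the four-month analysis is Jan, Jul, Aug, Sep).
#'
#' @param profile 12 x 3 matrix from [monthly_event_profile()].
#' @param k number of months to select.
#' @param months optional integer vector of month numbers that overrides
#'   the data-driven selection.
#' @return sorted integer vector of month numbers.
#' @export
select_months <- function(profile, k = 4L, months = NULL) {
  if (!is.null(months)) return(sort(as.integer(months)))
  diff <- abs(profile[, "high"] - profile[, "low"])
  eligible <- which(!is.na(diff))
  if (length(eligible) == 0L) stop("no month has both high and low cells")
  k <- min(k, length(eligible))
  sort(unname(eligible[order(diff[eligible], decreasing = TRUE)][seq_len(k)]))
}

#' Greatest temperature departure
#'
#' Of a week's mean maximum-temperature anomaly and mean minimum-temperature
#' anomaly, returns whichever has the larger absolute value, preserving its
#' sign.  Ties go to the maximum-temperature variable.  Vectorised; `NA` in
#' either input yields `NA`.
#'
#' @param max_anom,min_anom numeric vectors (degrees C).
#' @return numeric vector.
#' @export
greatest_departure <- function(max_anom, min_anom) {
  out <- ifelse(abs(max_anom) >= abs(min_anom), max_anom, min_anom)
  out[is.na(max_anom) | is.na(min_anom)] <- NA_real_
  out
}

#' Categorise temperature weeks as cool / normal / warm
#'
#' Within the supplied subset (typically the selected months), the lowest
#' `cool_share` fraction of weekly temperature-anomaly values is `cool` and
#' the highest `warm_share` fraction is `warm`, by type-7 percentile cuts;
#' the remainder is `normal`.
#'
#' @param values numeric weekly temperature anomalies (`NA` allowed,
#'   returned as `NA`).
#' @param cool_share,warm_share fractions in (0, 1) with sum < 1; defaults
#'   0.14 and 0.10.
#' @return factor with levels `cool`, `normal`, `warm` aligned to `values`.
#' @export
classify_temperature_weeks <- function(values, cool_share = 0.14,
                                       warm_share = 0.10) {
  if (cool_share <= 0 || warm_share <= 0 || cool_share + warm_share >= 1)
    stop("shares must be positive and sum to less than 1")
  ok <- !is.na(values)
  if (!any(ok)) stop("no classifiable values")
  cool_cut <- stats::quantile(values[ok], cool_share, type = 7, names = FALSE)
  warm_cut <- stats::quantile(values[ok], 1 - warm_share, type = 7, names = FALSE)
  lab <- rep(NA_character_, length(values))
  lab[ok] <- ifelse(values[ok] <= cool_cut, "cool",
                    ifelse(values[ok] >= warm_cut, "warm", "normal"))
  factor(lab, levels = c("cool", "normal", "warm"))
}

#' Contingency table of suicide classes by temperature categories
#'
#' Cross-tabulates day counts (3 suicide classes x 3 temperature
#' categories) and reports column percentages to one decimal, rounding half
#' away from zero.
#'
#' @param suicide_labels factor `high`/`normal`/`low`.
#' @param temp_labels factor `cool`/`normal`/`warm`, same days.
#' @return list of class `contingency_table`: `counts` (3 x 3 integer
#'   matrix, rows high/normal/low, columns cool/normal/warm), `col_pct`
#'   (column percentages, `NA` for empty columns), `total`.
#' @export
contingency <- function(suicide_labels, temp_labels) {
  if (length(suicide_labels) != length(temp_labels))
    stop("label vectors must cover a common day set")
  ok <- !is.na(suicide_labels) & !is.na(temp_labels)
  counts <- table(factor(suicide_labels[ok], levels = c("high", "normal", "low")),
                  factor(temp_labels[ok], levels = c("cool", "normal", "warm")))
  contingency_from_counts(unclass(counts))
}

#' Contingency percentages from a printed counts matrix
#'
#' @param counts 3 x 3 matrix of day counts (rows high/normal/low, columns
#'   cool/normal/warm).
#' @return `contingency_table` as in [contingency()].
#' @export
contingency_from_counts <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(3L, 3L))) stop("counts must be a 3 x 3 matrix")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (is.null(rownames(counts))) rownames(counts) <- c("high", "normal", "low")
  if (is.null(colnames(counts))) colnames(counts) <- c("cool", "normal", "warm")
  tot <- colSums(counts)
  pct <- sweep(counts, 2L, tot, "/") * 100
  pct[, tot == 0] <- NA_real_
  structure(list(counts = counts, col_pct = round_half_up(pct, 1L),
                 total = sum(counts)),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat("Day counts (suicide class x temperature category):\n")
  print(x$counts)
  cat("\nColumn percentages:\n")
  print(x$col_pct)
  invisible(x)
}
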