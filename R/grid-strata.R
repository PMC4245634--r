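# AIC sensitivity grid over (lag, lag df, exposure df) and stratified fits.

#' AIC sensitivity grid for the cross-basis model
#'
#' Fits one model per admissible combination of maximum lag, lag-polynomial
#' df and exposure-spline df.  Combinations with lag df exceeding the lag
#' are infeasible and reported as `NA` ("na" in the printed table).  All
#' fits share a common estimation sample (the first `max(lags)` days are
#' dropped for every fit) so AIC values are comparable across lags.
#'
#' @param counts a `daily_series` of counts.
#' @param exposure a `daily_series` of exposures (same calendar).
#' @param lags candidate maximum lags (default 3:6).
#' @param lag_dfs candidate lag-polynomial dfs (default 2:4).
#' @param exp_dfs candidate exposure-spline dfs (default 3:8).
#' @param model a [model_spec()].
#' @return list of class `aic_grid`: `table` (data frame with columns
#'   `lag`, `lag_df`, `exp_df`, `aic`, `status`), `best` (row of the
#'   minimum AIC), `n` (common sample size).
#' @export
aic_grid_search <- function(counts, exposure, lags = 3:6, lag_dfs = 2:4,
                            exp_dfs = 3:8, model = model_spec()) {
  stopifnot_daily(counts, "counts")
  stopifnot_daily(exposure, "exposure")
  check_aligned(counts, exposure)
  drop_first <- max(lags)
  grid <- expand.grid(lag = lags, lag_df = lag_dfs, exp_df = exp_dfs,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(grid$lag_df, grid$lag, grid$exp_df), ]
  rownames(grid) <- NULL
  grid$aic <- NA_real_
  grid$status <- "ok"
  n_common <- NA_integer_
  for (i in seq_len(nrow(grid))) {
    if (grid$lag_df[i] > grid$lag[i]) {
      grid$status[i] <- "na"
      next
    }
    fit <- tryCatch({
      cb <- build_cross_basis(exposure, exposure_spec(grid$exp_df[i]),
                              lag_spec(grid$lag[i], grid$lag_df[i]))
      fit_count_regression(counts, cb, model, drop_first = drop_first)
    }, error = function(e) e)
    if (inherits(fit, "error")) {
      grid$status[i] <- conditionMessage(fit)
    } else {
      grid$aic[i] <- fit$aic
      n_common <- fit$n
      if (!fit$converged) grid$status[i] <- "not converged"
    }
  }
  ok <- which(!is.na(grid$aic))
  if (length(ok) == 0L) stop("no grid cell could be fitted")
  best <- grid[ok[which.min(grid$aic[ok])], ]
  structure(list(table = grid, best = best, n = n_common), class = "aic_grid")
}

# ---- strata ----------------------------------------------------------------

season_of <- function(dates) {
  mo <- as.POSIXlt(dates)$mon + 1L
  c("winter", "winter", "spring", "spring", "spring", "summer", "summer",
    "summer", "fall", "fall", "fall", "winter")[mo]
}

# season year: December attaches to the following winter (Dec 1995 belongs
# to winter 1995/96, labelled by its starting year 1995)
season_year <- function(dates) {
  yr <- as.POSIXlt(dates)$year + 1900L
  mo <- as.POSIXlt(dates)$mon + 1L
  ifelse(mo == 12L, yr, ifelse(mo <= 2L & season_of(dates) == "winter",
                               yr - 1L, yr))
}

#' Stratum membership for an analysis scale
#'
#' `annual`: one stratum.  `biannual`: warm half Mar-Aug versus cold half
#' Sep-Feb (Dec-Feb attach forward to the stratum that started the previous
#' September).  `seasonal`: winter (Dec-Feb, December attaching forward),
#' spring (Mar-May), summer (Jun-Aug), fall (Sep-Nov).  `warm_season`: the
#' single Mar-Aug stratum.
#'
#' @param dates `Date` vector.
#' @param scale one of `annual`, `biannual`, `seasonal`, `warm_season`.
#' @return character vector of stratum names (`NA` for days outside any
#'   stratum, which only happens for `warm_season`).
#' @export
stratum_of <- function(dates, scale = c("annual", "biannual", "seasonal",
                                        "warm_season")) {
  scale <- match.arg(scale)
  mo <- as.POSIXlt(dates)$mon + 1L
  switch(scale,
    annual = rep("annual", length(dates)),
    biannual = ifelse(mo >= 3L & mo <= 8L, "warm_half", "cold_half"),
    seasonal = season_of(dates),
    warm_season = ifelse(mo >= 3L & mo <= 8L, "warm_season", NA_character_))
}

time_knots_for_scale <- function(scale) {
  switch(scale, annual = 11L, biannual = 5L, warm_season = 5L, seasonal = 3L)
}

#' Fit the cross-basis model within strata
#'
#' Subsets the data by stratum (the cross-basis is built on the full
#' contiguous series first so lagged exposures reach back across stratum
#' boundaries), fits the count regression per stratum with the scale's time
#' spline (interior knots 11/5/3 for annual/biannual/seasonal), and
#' predicts the cumulative RR curve against the stratum's median exposure.
#' Strata too small for the design are skipped with a warning.
#'
#' @param counts,exposure aligned `daily_series`.
#' @param scale analysis scale, see [stratum_of()].
#' @param e_spec,l_spec basis specifications.
#' @param grid_length points on the RR exposure grid.
#' @param quasipoisson passed to [model_spec()].
#' @return named list per stratum: `fit`, `rr`, `n`, `reference`.
#' @export
fit_strata <- function(counts, exposure, scale = "annual",
                       e_spec = exposure_spec(4L), l_spec = lag_spec(6L, 2L),
                       grid_length = 50L, quasipoisson = FALSE) {
  stopifnot_daily(counts, "counts")
  stopifnot_daily(exposure, "exposure")
  check_aligned(counts, exposure)
  strata <- stratum_of(counts$date, scale)
  model <- model_spec(time_knots = time_knots_for_scale(scale),
                      quasipoisson = quasipoisson)
  L <- l_spec$max_lag
  out <- list()
  for (s in unique(strata[!is.na(strata)])) {
    rows <- which(strata == s)
    rows <- rows[rows > L]                  # lag window needs history
    res <- tryCatch({
      sub_exp <- exposure$value[rows]
      cb_full <- build_cross_basis(exposure, exposure_spec(
        e_spec$df,
        knots = stats::quantile(sub_exp, seq_len(e_spec$df - 1L) / e_spec$df,
                                type = 7, names = FALSE),
        boundary = range(sub_exp)), l_spec)
      cb <- cb_full[rows, , drop = FALSE]
      attributes(cb) <- c(attributes(cb),
                          attributes(cb_full)[c("e_spec", "l_spec", "knots",
                                                "boundary", "lag_basis")])
      sub_counts <- counts[rows, ]
      class(sub_counts) <- class(counts)
      attr(sub_counts, "type") <- "count"
      fit <- fit_count_regression_noncontig(sub_counts, cb, model, index = rows)
      ref <- stats::median(sub_exp)
      rr <- predict_cumulative_rr(
        fit, cb, grid = seq(min(sub_exp), max(sub_exp),
                            length.out = grid_length), reference = ref)
      list(fit = fit, rr = rr, n = fit$n, reference = ref)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning(sprintf("stratum '%s' skipped: %s", s, conditionMessage(res)))
    } else {
      out[[s]] <- res
    }
  }
  out
}

# Like fit_count_regression but for stratum subsets whose dates are not
# contiguous; the time spline runs on the original day index.
fit_count_regression_noncontig <- function(counts, cb, model, index) {
  if (nrow(counts) != nrow(cb)) stop("counts and cross-basis are not aligned")
  Z <- model_design(counts$date, model, index)
  X <- cbind(cb, Z)
  fit <- fit_poisson_irls(counts$value, X, quasipoisson = model$quasipoisson)
  attr(fit, "cb_cols") <- colnames(cb)
  fit
}
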