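#' Simulation configuration for synthetic daily series
#'
#' Describes the generative model used by [simulate_temperature()] and
#' [simulate_counts()]: sinusoidal annual temperature cycles sharing one
#' AR(1) anomaly process, and Poisson daily counts whose log-rate combines a
#' baseline, an annual cycle, day-of-week offsets, and a distributed-lag
#' effect of the temperature anomaly.
#'
#' @param n_years number of whole civil years (>= 2).
#' @param tmean_max,tmean_min annual mean of daily maximum / minimum
#'   temperature (degrees C).
#' @param amp_max,amp_min annual-cycle amplitude of the maximum / minimum
#'   temperature (degrees C).
#' @param phase day-of-year at which the annual cycle peaks.
#' @param ar_rho AR(1) coefficient of the shared temperature anomaly, in
#'   `[0, 1)`.
#' @param ar_sigma innovation standard deviation of the anomaly (degrees C).
#' @param base_rate expected counts per day (> 0) before seasonal,
#'   day-of-week and temperature effects.
#' @param season_amp dimensionless log-rate annual-cycle amplitude for the
#'   counts (same phase as the temperature cycle).
#' @param dow_effects seven log-rate offsets, Sunday through Saturday.
#' @param theta log rate ratio per degree C of temperature anomaly,
#'   cumulative over all lags (the lag weights distribute it).
#' @param lag_weights non-negative weights over lags `0..L`, summing to 1.
#' @param start_year first calendar year of the simulated period.
#' @param diurnal note: the max/min separation is implied by
#'   `tmean_max - tmean_min` and the amplitudes; no separate argument.
#' @param seed integer seed; temperature and counts use independent
#'   substreams derived from it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_years = 24L,
                       tmean_max = 13.2, tmean_min = 3.6,
                       amp_max = 13.5, amp_min = 12.5,
                       phase = 200,
                       ar_rho = 0.7, ar_sigma = 3.0,
                       base_rate = 1.23,
                       season_amp = 0.05,
                       dow_effects = c(0.05, 0.08, 0, -0.02, -0.03, -0.04, -0.04),
                       theta = 0,
                       lag_weights = rep(1 / 7, 7),
                       start_year = 1986L,
                       seed = 1L) {
  cfg <- list(n_years = as.integer(n_years), tmean_max = tmean_max,
              tmean_min = tmean_min, amp_max = amp_max, amp_min = amp_min,
              phase = phase, ar_rho = ar_rho, ar_sigma = ar_sigma,
              base_rate = base_rate, season_amp = season_amp,
              dow_effects = dow_effects, theta = theta,
              lag_weights = lag_weights, start_year = as.integer(start_year),
              seed = as.integer(seed))
  num <- c("tmean_max", "tmean_min", "amp_max", "amp_min", "phase",
           "ar_rho", "ar_sigma", "base_rate", "season_amp", "theta")
  for (f in num) {
    if (length(cfg[[f]]) != 1L || !is.finite(cfg[[f]]))
      stop(sprintf("field '%s' must be a single finite number", f))
  }
  if (any(!is.finite(cfg$dow_effects)) || length(cfg$dow_effects) != 7L)
    stop("field 'dow_effects' must be 7 finite log-rate offsets")
  if (any(!is.finite(cfg$lag_weights)) || any(cfg$lag_weights < 0))
    stop("field 'lag_weights' must be finite and non-negative")
  if (abs(sum(cfg$lag_weights) - 1) > 1e-12)
    stop("field 'lag_weights' must sum to 1")
  if (cfg$n_years < 2L) stop("field 'n_years' must be >= 2")
  if (cfg$ar_rho < 0 || cfg$ar_rho >= 1) stop("field 'ar_rho' must be in [0, 1)")
  if (cfg$ar_sigma < 0) stop("field 'ar_sigma' must be >= 0")
  if (cfg$base_rate <= 0) stop("field 'base_rate' must be > 0")
  # shared anomaly means the cycles alone must keep tmax >= tmin on every day
  if (cfg$tmean_max - cfg$tmean_min < abs(cfg$amp_max - cfg$amp_min))
    stop("tmax cycle must dominate tmin cycle (tmean gap < amplitude gap)")
  class(cfg) <- "sim_config"
  cfg
}

#' Named presets for the two study-site archetypes
#'
#' `"toronto_like"`: 24 years at 1.23 expected counts/day with a strong
#' midlatitude annual temperature cycle.  `"jackson_like"`: 27 years at 0.10
#' counts/day with a milder subtropical cycle.
#'
#' @param name preset name.
#' @param ... overrides passed on to [sim_config()].
#' @return A `sim_config`.
#' @export
sim_preset <- function(name = c("toronto_like", "jackson_like"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    toronto_like = list(n_years = 24L, tmean_max = 13.2, tmean_min = 3.6,
                        amp_max = 13.5, amp_min = 12.5, ar_rho = 0.7,
                        ar_sigma = 3.0, base_rate = 1.23, start_year = 1986L),
    jackson_like = list(n_years = 27L, tmean_max = 24.6, tmean_min = 12.0,
                        amp_max = 9.5, amp_min = 8.5, ar_rho = 0.65,
                        ar_sigma = 2.5, base_rate = 0.10, start_year = 1980L))
  do.call(sim_config, utils::modifyList(base, list(...)))
}

# Derive independent substream seeds (< 2^31) from one master seed.
substream_seed <- function(seed, salt) {
  (as.double(seed) * 48271 + salt * 69621) %% 2147483647
}

annual_cycle <- function(dates, mean, amp, phase) {
  mean + amp * cos(2 * pi * (doy_index(dates) - phase) / 365.25)
}

#' Simulate daily maximum and minimum temperatures
#'
#' Each series is a sinusoidal annual cycle plus a single AR(1) anomaly
#' process shared between the two, which keeps `tmax >= tmin` structurally
#' whenever the cycles are ordered.  The AR(1) is initialised from its
#' stationary distribution.
#'
#' @param config a [sim_config()].
#' @return list with `daily_series` elements `tmax` and `tmin`, and the
#'   latent `anomaly` vector (the AR(1) process) for reference.
#' @export
simulate_temperature <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  dates <- year_calendar(config$start_year, config$n_years)
  n <- length(dates)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(substream_seed(config$seed, 1))
  a <- numeric(n)
  if (config$ar_sigma > 0) {
    a[1L] <- stats::rnorm(1, 0, config$ar_sigma / sqrt(1 - config$ar_rho^2))
    eps <- stats::rnorm(n - 1L, 0, config$ar_sigma)
    for (t in 2:n) a[t] <- config$ar_rho * a[t - 1L] + eps[t - 1L]
  }
  tmax <- annual_cycle(dates, config$tmean_max, config$amp_max, config$phase) + a
  tmin <- annual_cycle(dates, config$tmean_min, config$amp_min, config$phase) + a
  list(tmax = daily_series(dates, tmax, "temperature"),
       tmin = daily_series(dates, tmin, "temperature"),
       anomaly = a)
}

#' Simulate daily counts given simulated temperatures
#'
#' Counts are Poisson with log-rate
#' `log(base_rate) + season_amp * cos(2*pi*(doy - phase)/365.25) +
#'  dow_effect + theta * sum_l w_l * anomaly(t - l)`,
#' where `anomaly` is the temperature's deviation from its noise-free annual
#' cycle (the latent AR(1) process).  For the first `L` days the available
#' lag weights are renormalised to sum to 1 so the series keeps full length.
#'
#' @param temps result of [simulate_temperature()] (calendar must match the
#'   config).
#' @param config the same [sim_config()].
#' @return `daily_series` of counts.
#' @export
simulate_counts <- function(temps, config) {
  stopifnot(inherits(config, "sim_config"))
  dates <- temps$tmax$date
  expect_dates <- year_calendar(config$start_year, config$n_years)
  if (length(dates) != length(expect_dates) || any(dates != expect_dates))
    stop("temperature calendar does not match the configuration")
  n <- length(dates)
  w <- config$lag_weights
  L <- length(w) - 1L
  a <- temps$anomaly
  lagged <- numeric(n)
  for (t in seq_len(n)) {
    l_max <- min(L, t - 1L)
    ww <- w[1:(l_max + 1L)]
    ww <- ww / sum(ww)
    lagged[t] <- sum(ww * a[t - (0:l_max)])
  }
  dow <- as.POSIXlt(dates)$wday + 1L   # 1 = Sunday
  lograte <- log(config$base_rate) +
    config$season_amp * cos(2 * pi * (doy_index(dates) - config$phase) / 365.25) +
    config$dow_effects[dow] +
    config$theta * lagged
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(substream_seed(config$seed, 2))
  daily_series(dates, stats::rpois(n, exp(lograte)), "count")
}

#' Simulate a full daily bundle (temperatures and counts)
#'
#' @param config a [sim_config()] or preset name accepted by [sim_preset()].
#' @param ... overrides when `config` is a preset name.
#' @return list with `tmax`, `tmin`, `count` daily series and the config.
#' @export
simulate_daily <- function(config = "toronto_like", ...) {
  if (is.character(config)) config <- sim_preset(config, ...)
  temps <- simulate_temperature(config)
  counts <- simulate_counts(temps, config)
  list(tmax = temps$tmax, tmin = temps$tmin, count = counts, config = config)
}
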