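# Poisson log-link regression by iteratively reweighted least squares.
# Written out explicitly (rather than delegating to stats::glm) because the
# cross-basis fit, its covariance and its AIC are the core of the package;
# tests check the solution against independent numerical optimisation.

#' Model specification for the count regression
#'
#' @param time_knots number of equally spaced interior knots for the natural
#'   cubic time spline over the stratum's date span: 11 (annual), 5
#'   (biannual) or 3 (seasonal) by convention; 0 drops the time term.
#' @param day_of_week include 6 day-of-week indicator contrasts
#'   (reference Sunday)?
#' @param quasipoisson inflate the covariance by the Pearson dispersion
#'   (affects confidence intervals only, not coefficients or AIC)?
#' @return list of class `model_spec`.
#' @export
model_spec <- function(time_knots = 11L, day_of_week = TRUE,
                       quasipoisson = FALSE) {
  time_knots <- as.integer(time_knots)
  if (time_knots < 0L) stop("time_knots must be >= 0")
  structure(list(time_knots = time_knots, day_of_week = day_of_week,
                 quasipoisson = quasipoisson), class = "model_spec")
}

# Time-spline + day-of-week design columns for a set of dates.  `index`
# is the day position within the full series so that subsetted strata keep
# a common clock.
model_design <- function(dates, spec, index = seq_along(dates)) {
  cols <- NULL
  if (spec$time_knots > 0L) {
    rng <- range(index)
    knots <- seq(rng[1L], rng[2L], length.out = spec$time_knots + 2L)
    knots <- knots[-c(1L, length(knots))]
    ts <- splines::ns(index, knots = knots, Boundary.knots = rng)
    ts <- matrix(as.numeric(ts), nrow = length(index))
    colnames(ts) <- paste0("time_s", seq_len(ncol(ts)))
    cols <- ts
  }
  if (spec$day_of_week) {
    wd <- as.POSIXlt(dates)$wday           # 0 = Sunday (reference)
    dow <- sapply(1:6, function(d) as.numeric(wd == d))
    colnames(dow) <- paste0("dow_", c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat"))
    cols <- cbind(cols, dow)
  }
  cols
}

#' Poisson log-link fit by iteratively reweighted least squares
#'
#' Maximises the Poisson log-likelihood of `y` given the design `X`
#' (an intercept is prepended).  Convergence is declared when the relative
#' deviance change falls below `tol` (default 1e-10) within `max_iter`
#' iterations.  The covariance is the inverse observed information
#' `(X'WX)^{-1}`.
#'
#' @param y non-negative integer response.
#' @param X design matrix without intercept (NA rows are dropped from the
#'   fit together with their responses).
#' @param tol,max_iter IRLS stopping rule.
#' @param quasipoisson scale the covariance by the Pearson dispersion.
#' @return list of class `count_fit`: `coef`, `vcov`, `loglik`, `aic`,
#'   `n`, `converged`, `dispersion`, `kept` (logical row filter).
#' @export
fit_poisson_irls <- function(y, X, tol = 1e-10, max_iter = 100L,
                             quasipoisson = FALSE) {
  X <- cbind(`(Intercept)` = rep(1, length(y)), X)
  kept <- stats::complete.cases(X) & !is.na(y)
  Xf <- X[kept, , drop = FALSE]
  yf <- y[kept]
  if (any(yf < 0)) stop("response must be non-negative")
  qrX <- qr(Xf)
  if (qrX$rank < ncol(Xf)) {
    drop_idx <- qrX$pivot[(qrX$rank + 1L):ncol(Xf)]
    stop(sprintf("design is rank deficient; collinear columns: %s",
                 paste(colnames(Xf)[drop_idx], collapse = ", ")))
  }
  n <- nrow(Xf)
  p <- ncol(Xf)
  eta <- log(pmax(yf, 0.5))                 # standard mu-initialisation
  dev_old <- Inf
  converged <- FALSE
  beta <- NULL
  for (iter in seq_len(max_iter)) {
    mu <- exp(eta)
    w <- mu                                 # Poisson log link: W = mu
    z <- eta + (yf - mu) / mu
    fit <- stats::lm.wfit(Xf, z, w)
    beta <- fit$coefficients
    eta <- drop(Xf %*% beta)
    mu <- exp(eta)
    dev <- 2 * sum(ifelse(yf > 0, yf * log(yf / mu), 0) - (yf - mu))
    if (is.finite(dev) && abs(dev - dev_old) / (abs(dev) + 0.1) < tol) {
      converged <- TRUE
      break
    }
    dev_old <- dev
  }
  mu <- exp(drop(Xf %*% beta))
  XtWX <- crossprod(Xf * sqrt(mu))
  vcov <- chol2inv(chol(XtWX))
  dispersion <- 1
  if (quasipoisson && n > p)
    dispersion <- sum((yf - mu)^2 / mu) / (n - p)
  vcov <- vcov * dispersion
  dimnames(vcov) <- list(colnames(Xf), colnames(Xf))
  loglik <- sum(stats::dpois(yf, mu, log = TRUE))
  structure(list(coef = stats::setNames(beta, colnames(Xf)), vcov = vcov,
                 loglik = loglik, aic = -2 * loglik + 2 * p, n = n,
                 converged = converged, dispersion = dispersion, kept = kept),
            class = "count_fit")
}

#' Fit the cross-basis count regression
#'
#' Assembles intercept + cross-basis + time spline + day-of-week design and
#' fits the Poisson log-link model.  Rows lost to the lag window (leading
#' `NA` cross-basis rows) are dropped; `drop_first` can force a larger
#' common estimation sample for AIC comparability across lag choices.
#'
#' @param counts a `daily_series` of counts.
#' @param cb a [build_cross_basis()] matrix aligned with `counts`.
#' @param model a [model_spec()].
#' @param drop_first drop this many leading days regardless of the lag
#'   (default: the cross-basis' own max lag).
#' @param index day positions within the full series (for strata).
#' @return `count_fit` with the cross-basis column names recorded in
#'   attribute `cb_cols`.
#' @export
fit_count_regression <- function(counts, cb, model = model_spec(),
                                 drop_first = NULL, index = NULL) {
  stopifnot_daily(counts, "counts")
  if (nrow(counts) != nrow(cb)) stop("counts and cross-basis are not aligned")
  if (is.null(index)) index <- seq_len(nrow(counts))
  Z <- model_design(counts$date, model, index)
  X <- cbind(cb, Z)
  if (!is.null(drop_first) && drop_first > 0L) {
    X[seq_len(drop_first), ] <- NA_real_
  }
  fit <- fit_poisson_irls(counts$value, X, quasipoisson = model$quasipoisson)
  attr(fit, "cb_cols") <- colnames(cb)
  fit
}
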