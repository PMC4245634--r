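test_that("lag basis is the polynomial design in the lag number", {
  P <- make_lag_basis(lag_spec(6L, 3L))
  expect_equal(dim(P), c(7L, 3L))
  expect_equal(P[3L, ], c(1, 2, 4))             # row for l = 2
  expect_true(all(P[, 1L] == 1))                # intercept column
  expect_error(lag_spec(3L, 4L), "na")          # infeasible cell
})

test_that("exposure basis spans natural cubic splines on its knots", {
  set.seed(14)
  x <- runif(300, -10, 30)
  spec <- exposure_spec(5L)
  B <- make_exposure_basis(x, spec)
  knots <- c(attr(B, "boundary")[1L], attr(B, "knots"), attr(B, "boundary")[2L])
  # a function that IS a natural cubic spline on the same knots
  f <- stats::splinefun(knots, c(0.3, -1, 2, 0.5, -0.7, 1.4), method = "natural")
  fit <- lm.fit(cbind(1, B), f(x))
  expect_lt(max(abs(fit$residuals)), 1e-8)
})

test_that("exposure basis is linear beyond the boundary knots", {
  x <- seq(0, 10, by = 0.5)
  B <- make_exposure_basis(x, exposure_spec(4L, boundary = c(3, 7)))
  out <- seq(10, 20, by = 0.25)                  # strictly beyond boundary
  Bo <- make_exposure_basis(out,
                            exposure_spec(4L, knots = attr(B, "knots"),
                                          boundary = attr(B, "boundary")))
  d2 <- diff(Bo, differences = 2)
  expect_lt(max(abs(d2)), 1e-6)
  expect_error(make_exposure_basis(rep(1, 50), exposure_spec(3L)), "distinct")
})

test_that("cross-basis rows equal the brute-force double loop", {
  set.seed(6)
  for (case in list(c(6L, 2L, 3L), c(4L, 4L, 5L), c(3L, 3L, 8L))) {
    x <- rnorm(150, 10, 6)
    e_spec <- exposure_spec(case[3L])
    l_spec <- lag_spec(case[1L], case[2L])
    cb <- build_cross_basis(x, e_spec, l_spec)
    expect_equal(ncol(cb), case[2L] * case[3L])
    oracle <- brute_cross_basis(x, e_spec, l_spec)
    expect_true(all(is.na(cb[seq_len(case[1L]), ])))
    expect_lt(max(abs(cb - oracle), na.rm = TRUE), 1e-10)
    expect_identical(unname(is.na(unclass(cb))), is.na(oracle))
  }
})

test_that("missing exposure invalidates the trailing lag windows", {
  set.seed(8)
  x <- rnorm(60, 5, 3)
  x[30] <- NA
  cb <- build_cross_basis(x, exposure_spec(3L), lag_spec(4L, 2L))
  expect_true(all(is.na(cb[30:34, ])))
  expect_false(anyNA(cb[35:60, ]))
})

test_that("intercept-only Poisson fit recovers the closed-form MLE", {
  fit <- fit_poisson_irls(c(1, 2, 3), NULL)
  expect_equal(unname(fit$coef), log(2), tolerance = 1e-9)
  expect_true(fit$converged)
  expect_equal(fit$aic, -2 * fit$loglik + 2)     # AIC identity
})

test_that("IRLS agrees with an independent numerical likelihood optimizer", {
  set.seed(19)
  n <- 200L
  X <- cbind(rnorm(n), runif(n), rbinom(n, 1, 0.4))
  colnames(X) <- c("a", "b", "c")
  beta_true <- c(0.2, 0.5, -0.8, 0.3)
  y <- rpois(n, exp(cbind(1, X) %*% beta_true))
  fit <- fit_poisson_irls(y, X)
  negll <- function(b) -sum(stats::dpois(y, exp(cbind(1, X) %*% b), log = TRUE))
  opt <- stats::optim(rep(0, 4), negll, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  expect_lt(max(abs(unname(fit$coef) - opt$par)), 1e-6)
  # and with the reference implementation, including the covariance
  g <- stats::glm(y ~ X, family = poisson())
  expect_equal(unname(fit$coef), unname(coef(g)), tolerance = 1e-8)
  expect_equal(unname(fit$vcov), unname(vcov(g)), tolerance = 1e-4)
  expect_equal(fit$loglik, as.numeric(logLik(g)), tolerance = 1e-8)
  expect_equal(fit$aic, AIC(g), tolerance = 1e-6)
})

test_that("rank-deficient designs are rejected naming the collinear column", {
  set.seed(22)
  X <- cbind(a = rnorm(50), b = rnorm(50))
  X <- cbind(X, dup = X[, "a"])
  expect_error(fit_poisson_irls(rpois(50, 2), X), "dup")
})

test_that("RR curve is exactly 1 with zero SE at the reference", {
  b <- simulate_daily("toronto_like", n_years = 3L, seed = 4L)
  cb <- build_cross_basis(b$tmax, exposure_spec(4L), lag_spec(6L, 2L))
  fit <- fit_count_regression(b$count, cb, model_spec(11L))
  ref <- median(b$tmax$value)
  rr <- predict_cumulative_rr(fit, cb, grid = c(ref - 5, ref, ref + 5),
                              reference = ref)
  expect_equal(rr$rr[2L], 1.0)
  expect_equal(rr$se_log[2L], 0.0)
  expect_true(all(rr$lo <= rr$rr & rr$rr <= rr$hi))
  expect_true(all(rr$rr > 0))
  # all cross-basis coefficients zero -> flat curve at 1
  fit0 <- fit
  cbn <- attr(fit, "cb_cols")
  fit0$coef[cbn] <- 0
  fit0$vcov[cbn, ] <- 0
  fit0$vcov[, cbn] <- 0
  rr0 <- predict_cumulative_rr(fit0, cb, reference = ref)
  expect_true(all(abs(rr0$rr - 1) < 1e-12))
  expect_true(all(rr0$se_log == 0))
})

test_that("RR curve is invariant to a constant exposure shift", {
  b <- simulate_daily("toronto_like", n_years = 3L, seed = 15L)
  cb1 <- build_cross_basis(b$tmax, exposure_spec(4L), lag_spec(6L, 2L))
  fit1 <- fit_count_regression(b$count, cb1, model_spec(5L))
  ref <- median(b$tmax$value)
  g <- seq(quantile(b$tmax$value, 0.05), quantile(b$tmax$value, 0.95),
           length.out = 20L)
  rr1 <- predict_cumulative_rr(fit1, cb1, grid = g, reference = ref)
  shift <- 100
  shifted <- daily_series(b$tmax$date, b$tmax$value + shift)
  cb2 <- build_cross_basis(shifted, exposure_spec(4L), lag_spec(6L, 2L))
  fit2 <- fit_count_regression(b$count, cb2, model_spec(5L))
  rr2 <- predict_cumulative_rr(fit2, cb2, grid = g + shift,
                               reference = ref + shift)
  expect_equal(rr2$rr, rr1$rr, tolerance = 1e-8)
  expect_equal(rr2$lo, rr1$lo, tolerance = 1e-6)
})

test_that("AIC grid has the full layout with infeasible cells marked na", {
  b <- simulate_daily("toronto_like", n_years = 3L, seed = 33L)
  grid <- aic_grid_search(b$count, b$tmax, exp_dfs = c(3L, 4L))
  tab <- grid$table
  expect_equal(nrow(tab), 4L * 3L * 2L)
  na_cells <- tab[tab$lag == 3L & tab$lag_df == 4L, ]
  expect_true(all(na_cells$status == "na"))
  expect_true(all(is.na(na_cells$aic)))
  expect_true(all(tab$status[tab$lag_df <= tab$lag] == "ok"))
  expect_equal(grid$best$aic, min(tab$aic, na.rm = TRUE))
  # single admissible cell returns that cell
  g1 <- aic_grid_search(b$count, b$tmax, lags = 6L, lag_dfs = 2L, exp_dfs = 3L)
  expect_equal(nrow(g1$table), 1L)
  expect_equal(g1$best$lag, 6L)
})

test_that("stratum conventions: winter attachment, warm season, partition", {
  expect_equal(stratum_of(as.Date("1995-12-15"), "seasonal"), "winter")
  expect_equal(anomalag:::season_year(as.Date("1995-12-15")), 1995L)
  expect_equal(anomalag:::season_year(as.Date("1996-01-15")), 1995L)
  expect_equal(stratum_of(as.Date("1995-03-01"), "warm_season"), "warm_season")
  expect_true(is.na(stratum_of(as.Date("1995-09-01"), "warm_season")))
  dates <- year_calendar(1995L, 2L)
  seas <- stratum_of(dates, "seasonal")
  expect_false(anyNA(seas))
  expect_setequal(unique(seas), c("winter", "spring", "summer", "fall"))
  bi <- stratum_of(dates, "biannual")
  expect_false(anyNA(bi))
})

test_that("stratified fits produce one RR curve per stratum", {
  b <- simulate_daily("toronto_like", n_years = 4L, seed = 27L)
  out <- fit_strata(b$count, b$tmax, scale = "seasonal",
                    e_spec = exposure_spec(3L), grid_length = 10L)
  expect_setequal(names(out), c("winter", "spring", "summer", "fall"))
  for (s in names(out)) {
    expect_true(out[[s]]$fit$converged)
    rr <- out[[s]]$rr
    expect_true(all(rr$lo <= rr$rr & rr$rr <= rr$hi))
    expect_equal(attr(rr, "reference"), out[[s]]$reference)
  }
  warm <- fit_strata(b$count, b$tmax, scale = "warm_season",
                     e_spec = exposure_spec(3L), grid_length = 5L)
  expect_equal(names(warm), "warm_season")
})
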