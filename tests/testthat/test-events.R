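weekly_df <- function(values, start = "2001-01-01") {
  data.frame(date = seq(as.Date(start), by = "day",
                        length.out = length(values)),
             value = values)
}

test_that("suicide-week percentile classification matches a sort-based oracle", {
  set.seed(3)
  w <- weekly_df(sample(1:100))
  cls <- classify_suicide_weeks(w)
  expect_identical(sum(cls$labels == "high", na.rm = TRUE), 5L)   # top 5%
  expect_identical(sum(cls$labels == "low", na.rm = TRUE), 5L)
  expect_setequal(w$value[cls$labels == "high"], 96:100)
  expect_setequal(w$value[cls$labels == "low"], 1:5)
  # thresholds are the type-7 percentiles of the eligible values
  expect_equal(unname(cls$thresholds),
               unname(quantile(w$value, c(0.05, 0.95), type = 7)))
  # every eligible day gets exactly one label
  expect_false(anyNA(cls$labels))
})

test_that("degenerate all-equal weekly values are all 'normal'", {
  cls <- classify_suicide_weeks(weekly_df(rep(2.5, 50)))
  expect_true(all(cls$labels == "normal"))
  expect_equal(unname(cls$thresholds), c(2.5, 2.5))
})

test_that("classification preconditions", {
  expect_error(classify_suicide_weeks(weekly_df(rep(NA_real_, 50))),
               "eligible")
  expect_error(classify_suicide_weeks(weekly_df(1:20)), "40")
  expect_error(classify_suicide_weeks(weekly_df(1:50), low_q = 95, high_q = 5))
})

test_that("realized high/low shares calibrate to 5% on synthetic data", {
  b <- simulate_daily("toronto_like", n_years = 10L, seed = 17L)
  clim <- build_climatology(b$count)
  wk <- weekly_aggregate(compute_anomalies(b$count, clim), "sum")
  cls <- classify_suicide_weeks(wk)
  n <- sum(!is.na(cls$labels))
  expect_lt(abs(mean(cls$labels == "high", na.rm = TRUE) - 0.05), 0.02)
  expect_lt(abs(mean(cls$labels == "low", na.rm = TRUE) - 0.05), 0.02)
})

test_that("monthly event profile equals brute-force filtered means", {
  set.seed(9)
  n <- 500L
  w <- weekly_df(rnorm(n), "2001-01-01")
  labels <- factor(sample(c("high", "normal", "low"), n, TRUE,
                          prob = c(0.05, 0.9, 0.05)),
                   levels = c("high", "normal", "low"))
  prof <- monthly_event_profile(w, labels)
  mo <- as.POSIXlt(w$date)$mon + 1L
  for (m in sample(1:12, 4L)) {
    for (cl in c("high", "low")) {
      sel <- mo == m & labels == cl
      expected <- if (any(sel)) mean(w$value[sel]) else NA_real_
      expect_equal(unname(prof[m, cl]), expected)
    }
    sel <- mo == m & labels == "normal"
    expect_equal(unname(prof[m, "other"]),
                 if (any(sel)) mean(w$value[sel]) else NA_real_)
  }
  # all-zero anomalies give all-zero cells
  z <- monthly_event_profile(weekly_df(rep(0, n)), labels)
  expect_true(all(z[!is.na(z)] == 0))
})

test_that("singleton class cell equals its one observation", {
  w <- weekly_df(rep(0, 366), "2004-01-01")
  w$value[200] <- 2.5                            # 2004-07-18
  labels <- factor(rep("normal", 366), levels = c("high", "normal", "low"))
  labels[200] <- "high"
  prof <- monthly_event_profile(w, labels)
  expect_equal(unname(prof["Jul", "high"]), 2.5)
})

test_that("month selection ranks |high - low| with override support", {
  prof <- matrix(NA_real_, 12, 3,
                 dimnames = list(month.abb, c("high", "low", "other")))
  prof[, "low"] <- 0
  prof[, "high"] <- c(5, 1, 1, 1, 1, 1, 4, 3, 2, 0, 0, 0)
  expect_identical(select_months(prof, 4L), c(1L, 7L, 8L, 9L))
  expect_identical(select_months(prof, 12L), 1:12)
  expect_identical(select_months(prof, 4L, months = c(2, 3)), c(2L, 3L))
  # random profiles against a brute-force sort
  set.seed(5)
  for (i in 1:5) {
    prof[, "high"] <- rnorm(12)
    prof[, "low"] <- rnorm(12)
    d <- abs(prof[, "high"] - prof[, "low"])
    expect_setequal(select_months(prof, 3L),
                    order(d, decreasing = TRUE)[1:3])
  }
  # months with an empty high or low cell are excluded from ranking
  prof[1, "high"] <- NA
  expect_false(1L %in% select_months(prof, 12L))
})

test_that("greatest departure keeps the larger magnitude, sign preserved", {
  expect_equal(greatest_departure(2.0, -1.0), 2.0)
  expect_equal(greatest_departure(-3.0, 2.0), -3.0)
  expect_equal(greatest_departure(-2.0, 2.0), -2.0)  # tie -> max variable
  expect_true(is.na(greatest_departure(NA, 2.0)))
  got <- greatest_departure(c(1, -4, NA), c(-2, 3, 1))
  expect_equal(got, c(-2, -4, NA))
})

test_that("temperature-week categories hit the configured shares", {
  set.seed(2)
  v <- sample(1:100)
  lab <- classify_temperature_weeks(v)
  expect_identical(as.integer(table(lab)), c(14L, 76L, 10L))
  expect_setequal(v[lab == "cool"], 1:14)
  expect_setequal(v[lab == "warm"], 91:100)
  # symmetric shares on a symmetric distribution give symmetric counts
  lab2 <- classify_temperature_weeks(v, 0.2, 0.2)
  expect_equal(sum(lab2 == "cool"), sum(lab2 == "warm"))
  expect_error(classify_temperature_weeks(v, 0.6, 0.5), "shares")
})

test_that("contingency tables cross-tabulate and percentage correctly", {
  s <- factor(c("high", "high", "normal", "low", NA),
              levels = c("high", "normal", "low"))
  t <- factor(c("warm", "cool", "cool", "cool", "warm"),
              levels = c("cool", "normal", "warm"))
  ct <- contingency(s, t)
  expect_equal(ct$total, 4)                      # NA days drop out
  expect_equal(unname(ct$counts["high", "cool"]), 1)
  expect_equal(unname(ct$col_pct[, "cool"]), c(33.3, 33.3, 33.3))
  expect_true(all(is.na(ct$col_pct[, "normal"])))  # empty column undefined
  # single-cell table is 100%
  one <- contingency(factor(rep("high", 3), levels = c("high", "normal", "low")),
                     factor(rep("warm", 3), levels = c("cool", "normal", "warm")))
  expect_equal(unname(one$col_pct["high", "warm"]), 100.0)
  # column percentages sum to 100 within rounding
  for (block in table1_counts) {
    p <- contingency_from_counts(block)$col_pct
    expect_true(all(abs(colSums(p) - 100) <= 0.2))
  }
})

test_that("label partition and share calibration on a synthetic run", {
  b <- simulate_daily("toronto_like", n_years = 6L, seed = 23L)
  clims <- lapply(b[c("count", "tmax", "tmin")], build_climatology)
  wk_c <- weekly_aggregate(compute_anomalies(b$count, clims$count), "sum")
  wk_x <- weekly_aggregate(compute_anomalies(b$tmax, clims$tmax), "mean")
  wk_n <- weekly_aggregate(compute_anomalies(b$tmin, clims$tmin), "mean")
  cls <- classify_suicide_weeks(wk_c)
  gd <- greatest_departure(wk_x$value, wk_n$value)
  months <- (as.POSIXlt(wk_c$date)$mon + 1L) %in% c(1L, 7L, 8L, 9L)
  vals <- ifelse(months, gd, NA_real_)
  tl <- classify_temperature_weeks(vals)
  eligible <- !is.na(tl)
  expect_true(all(!is.na(cls$labels[eligible])))
  shares <- table(tl[eligible]) / sum(eligible)
  expect_lt(abs(shares[["cool"]] - 0.14), 0.03)
  expect_lt(abs(shares[["warm"]] - 0.10), 0.03)
  ct <- contingency(cls$labels[eligible], tl[eligible])
  expect_equal(ct$total, sum(eligible))
})
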