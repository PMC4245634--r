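# Shared fixtures and brute-force oracles, built in code at test time.

const_series <- function(value, n_years = 3L, start_year = 2001L,
                         type = "temperature") {
  dates <- year_calendar(start_year, n_years)
  daily_series(dates, rep(value, length(dates)), type)
}

# brute-force trailing-window aggregate, the oracle for weekly_aggregate()
brute_weekly <- function(values, stat = "sum", width = 7L) {
  n <- length(values)
  out <- rep(NA_real_, n)
  for (t in width:n) {
    win <- values[(t - width + 1L):t]
    if (!anyNA(win)) out[t] <- if (stat == "sum") sum(win) else mean(win)
  }
  out
}

# brute-force cross-basis entry, the oracle for build_cross_basis()
brute_cross_basis <- function(x, e_spec, l_spec) {
  B <- make_exposure_basis(x, e_spec)
  P <- make_lag_basis(l_spec)
  n <- length(x)
  J <- ncol(B)
  K <- ncol(P)
  L <- l_spec$max_lag
  cb <- matrix(NA_real_, n, J * K)
  for (t in (L + 1L):n) {
    for (k in seq_len(K)) {
      for (j in seq_len(J)) {
        s <- 0
        for (l in 0:L) s <- s + B[t - l, j] * P[l + 1L, k]
        cb[t, (k - 1L) * J + j] <- s
      }
    }
  }
  cb
}

# weighted lagged anomaly as the generator defines it (independent loop)
brute_lagged <- function(a, w) {
  L <- length(w) - 1L
  out <- numeric(length(a))
  for (t in seq_along(a)) {
    lmax <- min(L, t - 1L)
    ww <- w[1:(lmax + 1L)] / sum(w[1:(lmax + 1L)])
    out[t] <- sum(ww * a[t - (0:lmax)])
  }
  out
}

# published three-block day-count table
# (rows high/normal/low x columns cool/normal/warm)
t1_dimnames <- list(c("high", "normal", "low"), c("cool", "normal", "warm"))
table1_counts <- list(
  min      = matrix(c(3, 326, 27,  98, 2183, 69, 18, 222, 0), 3, 3,
                    dimnames = t1_dimnames),
  max      = matrix(c(2, 255, 22, 102, 2300, 74, 15, 176, 0), 3, 3,
                    dimnames = t1_dimnames),
  greatest = matrix(c(3, 387, 31,  89, 2089, 65, 27, 255, 0), 3, 3,
                    dimnames = t1_dimnames))

table1_pct <- list(
  min      = matrix(c(0.8, 91.6, 7.6, 4.2, 92.9, 2.9, 7.5, 92.5, 0.0), 3, 3),
  max      = matrix(c(0.7, 91.4, 7.9, 4.1, 92.9, 3.0, 7.9, 92.1, 0.0), 3, 3),
  greatest = matrix(c(0.7, 91.9, 7.4, 4.0, 93.1, 2.9, 9.6, 90.4, 0.0), 3, 3))
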