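# Exposure spline basis, lag polynomial basis, and their cross-basis.
# The exposure basis is a natural cubic spline (linear beyond the boundary
# knots); the lag basis is an ordinary polynomial in the lag number with an
# intercept column.  The cross-basis row for day t is
#   CB[t, (j,k)] = sum_{l=0..L} b_j(x[t-l]) * p_k(l),
# with exposure index j varying fastest in the column order.

#' Exposure basis specification
#'
#' @param df degrees of freedom of the natural cubic spline, 3..8.  Interior
#'   knots (df - 1 of them) sit at equally spaced quantiles of the data;
#'   boundary knots at the observed min/max, unless given explicitly.
#' @param knots,boundary optional explicit interior/boundary knots.
#' @return list of class `exposure_spec`.
#' @export
exposure_spec <- function(df = 3L, knots = NULL, boundary = NULL) {
  df <- as.integer(df)
  if (df < 3L || df > 8L) stop("exposure spline df must be in 3..8")
  structure(list(df = df, knots = knots, boundary = boundary),
            class = "exposure_spec")
}

#' Lag basis specification
#'
#' @param max_lag maximum lag L in days (lags 0..L), 3..6.
#' @param df polynomial degrees of freedom (including the intercept
#'   column), 2..4; must not exceed `max_lag` (the infeasible combination
#'   is reported as "na" in the AIC grid).
#' @return list of class `lag_spec`.
#' @export
lag_spec <- function(max_lag = 6L, df = 2L) {
  max_lag <- as.integer(max_lag)
  df <- as.integer(df)
  if (max_lag < 3L || max_lag > 6L) stop("max_lag must be in 3..6")
  if (df < 2L || df > 4L) stop("lag polynomial df must be in 2..4")
  if (df > max_lag)
    stop(sprintf("na: lag polynomial df %d unavailable at %d-day lag", df, max_lag))
  structure(list(max_lag = max_lag, df = df), class = "lag_spec")
}

#' Natural cubic spline exposure basis
#'
#' Evaluates a natural cubic spline basis (df columns, no intercept) at
#' `values`.  When `spec` carries no knots they are placed at equally
#' spaced quantiles of `values` with boundary knots at the range, and the
#' realised knots are attached to the result for later prediction.
#'
#' @param values numeric vector (NA rows propagate as NA).
#' @param spec an [exposure_spec()].
#' @return numeric matrix with attributes `knots`, `boundary`, `df`.
#' @export
make_exposure_basis <- function(values, spec) {
  stopifnot(inherits(spec, "exposure_spec"))
  obs <- values[!is.na(values)]
  if (length(unique(obs)) < spec$df)
    stop(sprintf("need at least %d distinct values for df = %d",
                 spec$df, spec$df))
  boundary <- spec$boundary
  if (is.null(boundary)) boundary <- range(obs)
  knots <- spec$knots
  if (is.null(knots)) {
    probs <- seq_len(spec$df - 1L) / spec$df
    # interior knots must sit inside the boundary interval
    inside <- obs[obs >= boundary[1L] & obs <= boundary[2L]]
    if (length(unique(inside)) < spec$df) inside <- pmin(pmax(obs, boundary[1L]), boundary[2L])
    knots <- stats::quantile(inside, probs, type = 7, names = FALSE)
  }
  if (any(knots < boundary[1L] | knots > boundary[2L]))
    stop("interior knots must lie within the boundary knots")
  b <- splines::ns(values, knots = knots, Boundary.knots = boundary)
  b <- matrix(as.numeric(b), nrow = length(values))
  attr(b, "knots") <- knots
  attr(b, "boundary") <- boundary
  attr(b, "df") <- spec$df
  b
}

#' Lag polynomial basis matrix
#'
#' Entry `(l, k)` is `l^k` for lags `l = 0..L` and powers `k = 0..df-1`
#' (an intercept column is included).
#'
#' @param spec a [lag_spec()].
#' @return `(L+1) x df` matrix.
#' @export
make_lag_basis <- function(spec) {
  stopifnot(inherits(spec, "lag_spec"))
  outer(0:spec$max_lag, 0:(spec$df - 1L), `^`)
}

#' Cross-basis matrix for distributed lag nonlinear modelling
#'
#' Column `(j, k)` at day `t` equals `sum_l b_j(x[t-l]) * p_k(l)`.  The
#' first `L` rows, and any row whose trailing window contains a missing
#' exposure, are `NA` and must be excluded from fitting.
#'
#' @param exposure a `daily_series` (or numeric vector) of exposures.
#' @param e_spec an [exposure_spec()].
#' @param l_spec a [lag_spec()].
#' @return matrix of class `cross_basis` with `n` rows and
#'   `e_spec$df * l_spec$df` columns; attributes store both specs, the
#'   realised exposure knots and the lag basis, for prediction.
#' @export
build_cross_basis <- function(exposure, e_spec, l_spec) {
  x <- if (is_daily_series(exposure)) exposure$value else as.numeric(exposure)
  L <- l_spec$max_lag
  if (length(x) < L + 1L) stop("exposure must cover at least L + 1 days")
  B <- make_exposure_basis(x, e_spec)       # n x J
  P <- make_lag_basis(l_spec)               # (L+1) x K
  n <- length(x)
  J <- ncol(B)
  K <- ncol(P)
  cb <- matrix(NA_real_, n, J * K)
  Bna <- B
  Bna[is.na(x), ] <- NA_real_
  for (k in seq_len(K)) {
    acc <- matrix(0, n, J)
    for (l in 0:L) {
      shifted <- rbind(matrix(NA_real_, l, J),
                       Bna[seq_len(n - l), , drop = FALSE])
      acc <- acc + shifted * P[l + 1L, k]
    }
    cb[, (k - 1L) * J + seq_len(J)] <- acc
  }
  colnames(cb) <- paste0("cb_e", rep(seq_len(J), K), "_l", rep(seq_len(K), each = J))
  structure(cb, class = c("cross_basis", "matrix"),
            e_spec = e_spec, l_spec = l_spec,
            knots = attr(B, "knots"), boundary = attr(B, "boundary"),
            lag_basis = P)
}

# Evaluate the stored exposure basis at new values (for RR prediction).
eval_exposure_basis <- function(cb, values) {
  b <- splines::ns(values, knots = attr(cb, "knots"),
                   Boundary.knots = attr(cb, "boundary"))
  matrix(as.numeric(b), nrow = length(values))
}
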