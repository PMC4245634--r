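---
title: "Weekly temperature anomalies and distributed lag count models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weekly temperature anomalies and distributed lag count models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anomalag)
```

# The problem

Daily counts of rare events — the motivating case is suicide deaths in a
metropolitan area, on the order of 0.1 to 1.2 per day — may respond to
short-term weather departures rather than to absolute temperature. This
package implements two complementary analyses of a daily record of maximum
temperature, minimum temperature and event counts:

1. **A descriptive track.** Each daily value is compared with the long-run
   mean for that calendar day (its *climatology*), giving a daily anomaly.
   Anomalies are aggregated over trailing seven-day windows (sums for
   counts, means for temperatures), high-end and low-end *count weeks* are
   identified by 5th/95th percentile cuts, and the co-occurrence of count
   weeks with cool/normal/warm temperature weeks is tabulated as a 3×3
   contingency table with column percentages.
2. **A model track.** A distributed lag nonlinear model (DLNM): daily
   counts are regressed on a *cross-basis* in temperature and lag, with a
   natural cubic time spline and day-of-week indicators as adjustment, and
   the fit is summarised as cumulative relative risk (RR) against the
   median temperature, with an AIC grid over the basis dimensions.

# The model

Let $x_t$ be the exposure (daily maximum or minimum temperature) and $y_t$
the daily count. The cross-basis combines an exposure basis
$b_1,\dots,b_J$ (natural cubic spline, $J \in 3..8$ degrees of freedom,
interior knots at equally spaced quantiles, boundary knots at the observed
range) with a lag basis $p_1,\dots,p_K$ (polynomials $p_k(l) = l^{k-1}$,
$K \in 2..4$, over lags $l = 0..L$, $L \in 3..6$):

$$\mathrm{CB}_{t,(j,k)} = \sum_{l=0}^{L} b_j(x_{t-l})\, p_k(l).$$

The count model is Poisson with log link,

$$\log \mu_t = \alpha + \sum_{j,k} \beta_{jk} \mathrm{CB}_{t,(j,k)}
  + s(t) + \gamma_{\mathrm{dow}(t)},$$

where $s$ is a natural cubic spline in the day index with 11 / 5 / 3
equally spaced interior knots for annual / biannual / seasonal analyses,
and $\gamma$ are six day-of-week contrasts against Sunday. Fitting is by
iteratively reweighted least squares (IRLS) to a relative deviance change
below $10^{-10}$ (at most 100 iterations); the covariance is the inverse
observed information, the AIC is $-2\ell + 2p$.

The cumulative (over lags) log relative risk of exposure $x$ against the
reference $x_0$ (the period median) is

$$\log \mathrm{RR}(x) = \sum_{j,k} \beta_{jk}\,[b_j(x) - b_j(x_0)]
  \sum_l p_k(l),$$

with variance from the same contrast vector and the coefficient
covariance, and a 95% interval $\exp(\log\mathrm{RR} \pm 1.96\,\mathrm{SE})$.
$\mathrm{RR}(x_0) = 1$ exactly with zero SE.

## Family choice

The source analyses describe a "general linear model" without naming the
family. Counts of rare daily events make the Poisson log-link the
defensible reading, and AIC comparison requires a true likelihood. A
quasi-Poisson dispersion correction is available as a flag
(`model_spec(quasipoisson = TRUE)`) and affects confidence intervals only.

# Conventions that matter

* **Day-of-year index.** Month-day stable: Feb 29 is always index 60,
  Mar 1 always 61, Dec 31 always 366. Feb 29's climatology therefore uses
  leap-year observations only; `smooth_halfwidth > 0` pools ±h neighbouring
  day-of-year positions (wrapping at the year end) and is the documented
  mitigation for its small sample.
* **Weeks.** Trailing windows $t-6..t$, daily-stepped and overlapping: one
  classification per eligible calendar day. The first six days and any
  window containing a missing temperature are undefined (missing days are
  never imputed). The temperature week is the same trailing window as the
  count week.
* **Percentiles.** Linear interpolation between order statistics
  (`quantile` type 7) everywhere. Count-week labels are inclusive
  (≥ 95th-percentile cut is high, ≤ 5th is low); when the two cuts
  coincide (degenerate all-equal input) all days are labelled normal,
  since the inclusive rule would otherwise double-label.
* **Count-week thresholds are computed on all months**; temperature
  categories (`cool` = lowest 14%, `warm` = highest 10% by default) are
  computed **within the selected months only** — this ordering matches
  the published bookkeeping the contingency test reproduces.
* **Greatest departure.** Of the weekly mean max- and min-temperature
  anomalies, the one with larger absolute value, sign preserved; exact
  ties go to the max-temperature variable (deterministic, measure-zero on
  real data).
* **Column percentages** are rounded half away from zero to one decimal
  (plain `round()` would give banker's rounding and miss printed values).
* **Strata.** Seasons are Dec–Feb / Mar–May / Jun–Aug / Sep–Nov with
  December attaching to the following winter; the warm season is Mar–Aug;
  the biannual scale is the warm half (Mar–Aug) against its complement.
  The cross-basis is built on the full contiguous series before
  subsetting, so lagged exposures reach back across stratum boundaries;
  each stratum uses its own median reference. Under-sized strata are
  skipped with a warning rather than failing the whole analysis.
* **AIC comparability.** All grid fits drop the first `max(lags)` days so
  every cell is estimated on the same sample; lag-polynomial df exceeding
  the lag is reported "na".
* **Time-spline knots** ("totaling 11, 5, 3") are read as interior knot
  counts, equally spaced over the stratum's day-index span; the count is a
  `model_spec` argument, so the alternative reading is one line away.

# The synthetic world

No raw data accompany the source analyses, so validation is against a
generator whose structure mirrors what the pipeline assumes:

* Temperatures: sinusoidal annual cycles for tmax and tmin (365.25-day
  period over the true civil calendar, so Feb 29 exists) plus a **shared**
  AR(1) anomaly process — the simplest process that keeps
  tmax ≥ tmin structurally. Defaults emulate a midlatitude record
  (tmax mean 13.2 °C, tmin 3.6 °C, amplitudes 13.5/12.5 °C, AR(1)
  ρ = 0.7, σ = 3 °C giving ≈ 4.2 °C anomaly SD).
* Counts: Poisson with log-rate = log(base rate) + seasonal cosine +
  day-of-week offset + θ · (lag-weighted temperature anomaly). θ is the
  *cumulative* log rate ratio per °C; the non-negative lag weights sum
  to 1 (uniform over lags 0..6 by default). The first L days renormalise
  the truncated weights so the series keeps full length.
* Presets: `toronto_like` (24 years at 1.23 counts/day, matching 10,772
  records over 1986–2009) and `jackson_like` (27 years at 0.10 counts/day,
  matching 989 records over 1980–2006). Day-of-week offsets default to a
  mild early-week peak (+0.08 Monday) and weekend deficit (−0.04), the
  qualitative pattern reported for suicide counts; the count seasonal
  amplitude defaults to 0.05 on the log scale.
* One integer seed drives two documented substreams (temperature, counts),
  so changing count parameters never perturbs the simulated weather.

What the generator does **not** emulate: reporting delays or miscounts,
multi-day heat-wave physiology beyond the linear-in-anomaly lag effect,
humidity/sunlight covariates, long-term trends in either series, or
spatial structure. A green end-to-end test therefore establishes that the
pipeline recovers the structure it assumes — not that the assumed
structure is true of any real city.

## Calibration worlds used by the stochastic tests

The null-calibration and parameter-recovery suites set the count seasonal
amplitude to zero (and the recovery world also flattens the temperature
annual cycle). Reason: the fitted time spline (11 interior knots over the
whole period) controls slow trends, not a within-year cycle, so a seasonal
count signal would sit outside the fitted family and the "true RR = 1"
premise would be false for reasons unrelated to the DLNM machinery. With
these worlds, pilot runs show the pointwise Wald intervals excluding
RR = 1 at 1.3% (4 simulated years), 6.1% (8 years) and 5.6% (16 years) of
central grid points — small-sample conservatism decaying toward the
nominal 5%. The acceptance test uses 8-year series, 200 replicates, a grid
restricted to the central 90% of the exposure range, and the a priori band
1%–10%. The recovery test uses cumulative θ = 0.35 per °C with uniform
weights, checking |bias| < 10% and ≥ 86% interval coverage over 50
replicates (the binomial band for a nominal 95% rate).

# Numerical choices

* IRLS initialises at log(max(y, 0.5)) and declares convergence on
  relative deviance change < 1e-10; rank deficiency is an error naming the
  collinear columns, not a silent drop.
* Interior exposure knots are constrained to the boundary interval; a
  request violating that is an error.
* RR grids beyond the boundary knots use the natural spline's linear tails
  and are flagged `extrapolated` rather than refused.
* CSV output prints doubles with `%.17g`, so write-then-read round trips
  are bitwise exact; this is what the determinism tests assert.

# Limitations

* Pointwise (not simultaneous) confidence bands; no penalised smoothing,
  case-crossover design, harvesting analysis beyond the 6-day lag, or
  spatial pooling.
* The contingency analysis reports no significance test, by design.
* Temperature categories are share-calibrated (14%/10%); if the original
  analysts used fixed anomaly cutoffs instead, realised shares would match
  but the cutoffs could differ — the printed bookkeeping cannot
  distinguish the two.
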