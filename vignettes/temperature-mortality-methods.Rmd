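---
title: "Modelling and projecting temperature-attributable mortality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and projecting temperature-attributable mortality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tempmort)
```

## The problem

Cold dominates the current temperature-related mortality burden in
high-latitude countries, but heat-related deaths are expected to grow as the
climate warms. Planning adaptation at the regional level requires three
things: a per-region estimate of the temperature–mortality association from
historical daily data, a way to turn that association into attributable
death counts, and a projection of those counts onto future temperature,
adaptation and population scenarios. This vignette describes how `tempmort`
does each step, which choices were genuinely open, and what the synthetic
data used in testing can and cannot demonstrate.

## Model

### Quasi-Poisson DLNM

Daily all-cause deaths $Y_t$ in a region are modelled as overdispersed
Poisson with

$$\log E[Y_t] = \alpha + f(x_t;\theta) + s(t;\beta) + \sum_p h_p(z_{pt};\gamma_p),$$

where $f$ is the distributed-lag cross-basis in daily mean temperature,
$s$ a smooth function of calendar time, and the $h_p$ day-of-week
indicators. Concretely:

* **Cross-basis.** A natural cubic spline in temperature (no intercept) is
  tensor-multiplied row-wise with a natural cubic spline in lag over days
  0–21 (with intercept). The 21-day window is long enough for multi-week
  cold effects and for short-term mortality displacement after heat. In the
  *fixed-knots* variant the temperature spline has internal knots at the
  10th/75th/90th percentiles of the region's fitting-period temperatures and
  the lag spline two internal knots; dimensions are then $4 \times 4 = 16$
  columns. The *qAIC-knots* variant scores a candidate grid (five
  temperature percentile sets crossed with 1–3 lag knots) by
  $\mathrm{qAIC} = -2\,\ell + 2p\hat\varphi$ and keeps the minimiser, with
  ties broken toward fewer degrees of freedom.
* **Trend.** A natural cubic spline of the day index with 7 df *per year*.
  The df rule could be read as 7 total; per-year is the convention in this
  literature and 7 total cannot control seasonality over an 18-year series,
  so per-year is used (`trend_df_per_year` is configurable).
* **Day of week.** Six indicators, Monday reference. The contrast choice is
  absorbed and irrelevant to the temperature terms.
* **Fitting.** Poisson IRLS to a relative tolerance of 1e-10 (at most 100
  iterations), Pearson dispersion $\hat\varphi = \sum (y-\hat\mu)^2/\hat\mu
  \,/\, (n-p)$, covariance $\hat\varphi \cdot \mathcal{I}^{-1}$.

Days with suppressed death counts are dropped from the likelihood, but their
temperatures still populate the lag windows of later days: the exposure is
fully observed, only the outcome is censored.

### Reduction, centring, attribution

Summing the lag-basis columns over lags 0–21 maps the $16$ cross-basis
coefficients to $4$ exposure-basis coefficients (and their covariance by the
same linear map): the *overall cumulative* curve, the log relative risk of a
sustained temperature accumulated over the lag window. The curve is centred
at the region's minimum-mortality temperature (MMT), fixed from prior
studies (16 °C in the south to 14 °C in the north) rather than re-estimated,
so RR(MMT) = 1 exactly with zero variance.

Attributable deaths on day $t$ are
$\mathrm{AN}_t = D_t\,(1 - e^{-\log \mathrm{RR}(T_t)})$, labelled heat when
$T_t$ is above the MMT and cold below it. The attribution deliberately uses
the lag-summed curve on same-day temperature (the forward-perspective
simplification): the attribution formula carries no lag index, and negative
AN is allowed wherever the fitted curve dips below 1 — several
low-population regions genuinely produce negative heat AN, and clamping
would bias aggregates. Decade totals are sums over closed calendar
ten-year intervals; AF is AN as a percentage of the same days' total
deaths; the end-of-century change ratio divides unrounded ANs and rounds
half-away-from-zero to one decimal last (computing from rounded ANs can
differ in the last decimal, which is why some published ratio columns do
not reproduce from their own printed ANs).

### Uncertainty

Confidence intervals are empirical 2.5th/97.5th percentiles (linear
interpolation) of decade ANs recomputed under multivariate-normal draws of
the reduced-curve coefficients; dispersion uncertainty is already inside
the scaled covariance. One RNG stream per call, governed by a seed, keeps
draws coherent across decades. The covariance square root uses Cholesky
with an eigenvalue fallback (negative eigenvalues clipped) for degenerate
matrices. In ensemble projections the draws are evaluated under every
member and pooled, so the interval reflects coefficient *and*
climate-model spread; the point estimate is the across-member mean. How to
combine these two uncertainty sources is not settled practice — pooling is
the simplest rule that uses both and degrades gracefully to the
single-member case.

### Scenario layers

* **Future baseline deaths.** A day-of-year climatology of observed deaths
  (suppressed days excluded; Feb 29 imputed as the Feb 28/Mar 1 average),
  scaled by a population factor interpolated linearly between five-year
  anchors and normalised to the baseline year. Holding age structure and
  death rates fixed is deliberately simplistic; trends in life expectancy
  are out of scope.
* **Adaptation.** A fraction $a$ of the heat-side *excess* risk is removed:
  $\mathrm{RR}' = 1 + (1-a)(\mathrm{RR}-1)$ above the MMT, cold untouched,
  constant over time. Scaling the excess (rather than RR or log RR, which
  the source conventions leave open) keeps adapted heat RR $\ge 1$ — scaling
  RR itself could make heat protective — and makes $a=1$ remove the heat
  burden exactly. A ramp-in over time would be easy to add but is not
  implemented; scenario levels are conventionally quoted as constants
  (0%, 20%, 50%).

## Synthetic data: what it emulates

The generator reproduces the statistical structure the analysis assumes,
with defaults chosen once to emulate a southern-Finland coastal region:

| parameter | default | why |
|---|---|---|
| annual mean temperature | 5 °C | Helsinki-like climate |
| seasonal amplitude / peak | 13 °C, day 205 | winter −8 °C to summer +18 °C means |
| AR(1) coefficient / sd | 0.7, 2.2 °C | multi-day synoptic persistence |
| baseline deaths | 15/day | large-county scale (~5 500/year) |
| cumulative RR at MMT+10 / MMT−20 | 1.3 / 1.4 | steep-but-plausible heat, flat cold per-degree risk |
| heat / cold lag decay | 2-day / 10-day mean lag | heat acute, cold multi-week |
| overdispersion | 1.5 | typical daily all-cause counts |
| trend amplitude / secular drift | 0.05 / −0.02 per decade (log) | modest non-temperature winter excess, slow decline |
| day-of-week | Sat −0.02, Sun −0.04 (log) | weekend registration deficit |
| censoring threshold | 3 | data-protection suppression rule |
| member warmings by 2100 | 2.2–5.5 °C / 5.8–9.1 °C | published multi-model scenario ranges |

Counts are negative binomial (NB2), the standard concrete law whose
mean–variance relation matches quasi-Poisson. The true log-RR surface is
piecewise linear about the MMT — the simplest shape with separately
identifiable heat and cold slopes — distributed over lags by normalised
profiles, so the cumulative curve equals the V exactly. Warming enters as a
linear ramp from zero at the baseline-decade midpoint (2015) to the
member's end-of-century warming at 2100. A 22-day burn-in is always
prepended so the analysis window starts with complete lag history, and a
low-rate region (1.5 deaths/day) demonstrates that censoring alone drives a
region over the >50%-missing exclusion threshold, as happened to the four
smallest counties.

What passing tests on these data do **not** show: robustness to urban heat
islands, influenza-season confounding of cold effects, age-structure
change, spatially correlated exposure across regions, or non-V true
surfaces. The generator has no spatial correlation and its trend is smooth
by construction.

## Numerical choices and edge cases

* Percentiles are type-7 (linear interpolation between order statistics).
* Exposure boundary knots are the observed fitting-period min/max;
  projected temperatures beyond them follow the natural spline's linear
  tails — no clamping, which is the standard extrapolation contract.
* Lag knots sit on the natural lag scale (log-spaced placement is covered
  by the qAIC candidate grid rather than hard-coded).
* The first 21 days of a series (incomplete lag window) are masked from the
  fit unless a temperature history is supplied.
* Rank deficiency is detected before fitting and reported with the
  offending columns; qAIC candidates that fail to fit are skipped with a
  warning, and selection errors only if all fail.
* Decades with zero total deaths make AF undefined and error; a zero or
  negative baseline AN makes the change ratio undefined (reported `NA`).
* A zero coefficient covariance collapses Monte-Carlo intervals onto the
  point estimate, which several limit tests rely on.

## Problem sizes used in the tests

The suite exercises the estimator at the study's native scale where it
matters and smaller elsewhere: parameter recovery uses 50 replicate
18-year series (pooled CI coverage of the true RR at MMT+10 and MMT−20,
accepted between 90% and 99%); null calibration uses 100 replicate 10-year
series with 300-draw intervals, testing mean AF against zero by z-test
(the curve's warm-tail anchor makes single-replicate AF noisy) and CI
coverage of zero; knot selection uses 100 replicate 6-year series with the
truth projected into the fixed-knots family; oracle-equivalence checks run
on 1000-day instances at 1e-9 and 50-point grids at 1e-8. These sizes are
the package's own trade-off between statistical resolution and a test
suite that runs in about a minute.

## Known limitations

Single-region fitting only — no BLUP/meta-regression pooling across
regions, which would stabilise small-county curves at the cost of
smoothing real regional differences. MMT is fixed, not estimated with
uncertainty. Attribution is forward-perspective on same-day temperature
rather than backward lag-resolved. The future death baseline ignores
demographic ageing and life-expectancy trends. Adaptation is a stipulated
constant, not a modelled process.
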