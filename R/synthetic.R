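# Synthetic study generator: seasonal temperatures with AR(1) noise, pseudo
# climate-model warming trajectories, overdispersed daily death counts driven
# by a known V-shaped exposure-lag-response surface plus smooth trend and
# day-of-week effects, data-protection censoring of small counts, and a
# five-year-step population path. Every generator is a pure function of its
# specification and seed.

#' Specification of a synthetic daily temperature climate
#'
#' Daily mean temperature = `annual_mean` + a seasonal cosine of amplitude
#' `seasonal_amplitude` peaking at day-of-year `peak_doy` + stationary AR(1)
#' noise with lag-1 correlation `ar1_coef` and marginal standard deviation
#' `noise_sd`. Defaults emulate a southern-Finland coastal climate.
#'
#' @param annual_mean degrees C (default 5).
#' @param seasonal_amplitude degrees C (default 13).
#' @param ar1_coef in (-1, 1) (default 0.7).
#' @param noise_sd marginal sd of the AR(1) noise, degrees C (default 2.2).
#' @param peak_doy day of year of the seasonal maximum (default 205, late
#'   July).
#' @param warming_by_2100 degrees C of warming reached at 2100 by a linear
#'   ramp starting at the 2010-2019 baseline midpoint (default 0).
#' @param seed integer seed.
#' @return a `climate_gen_spec`.
#' @export
climate_gen_spec <- function(annual_mean = 5, seasonal_amplitude = 13,
                             ar1_coef = 0.7, noise_sd = 2.2, peak_doy = 205,
                             warming_by_2100 = 0, seed = 1) {
  stopifnot(abs(ar1_coef) < 1, noise_sd > 0)
  structure(list(annual_mean = annual_mean,
                 seasonal_amplitude = seasonal_amplitude,
                 ar1_coef = ar1_coef, noise_sd = noise_sd,
                 peak_doy = peak_doy, warming_by_2100 = warming_by_2100,
                 seed = as.integer(seed)),
            class = "climate_gen_spec")
}

# Linear warming ramp: 0 up to the baseline-decade midpoint (2015-01-01),
# rising linearly to warming_by_2100 at 2100-01-01, constant after.
warming_ramp <- function(dates, warming_by_2100) {
  t0 <- as.numeric(as.Date("2015-01-01"))
  t1 <- as.numeric(as.Date("2100-01-01"))
  frac <- pmin(pmax((as.numeric(dates) - t0) / (t1 - t0), 0), 1)
  frac * warming_by_2100
}

#' Generate a daily temperature series
#'
#' @param spec a [climate_gen_spec()].
#' @param start,end first and last dates (inclusive).
#' @return data frame with `date`, `tmean`; deterministic given the spec's
#'   seed.
#' @export
gen_climate <- function(spec, start, end) {
  stopifnot(inherits(spec, "climate_gen_spec"))
  start <- as.Date(start); end <- as.Date(end)
  if (end <= start) stop("end must be after start")
  dates <- seq(start, end, by = 1)
  n <- length(dates)
  doy <- as.POSIXlt(dates)$yday + 1
  seasonal <- spec$seasonal_amplitude *
    cos(2 * pi * (doy - spec$peak_doy) / 365.25)
  set.seed(spec$seed)
  innov_sd <- spec$noise_sd * sqrt(1 - spec$ar1_coef^2)
  noise <- as.numeric(stats::filter(stats::rnorm(n, 0, innov_sd),
                                    spec$ar1_coef, method = "recursive"))
  tmean <- spec$annual_mean + seasonal + noise +
    warming_ramp(dates, spec$warming_by_2100)
  data.frame(date = dates, tmean = tmean)
}

#' Generate a pseudo climate-model ensemble for a scenario
#'
#' Each member is a [gen_climate()] draw plus its own linear warming ramp;
#' member end-of-century warmings are spread evenly across `warming_range`
#' (published multi-model ranges: 2.2-5.5 degrees C for SSP2-4.5 and 5.8-9.1
#' for SSP5-8.5).
#'
#' @param base_spec a [climate_gen_spec()] supplying climate parameters.
#' @param scenario_id scenario label.
#' @param warming_range length-2 range of member warmings by 2100.
#' @param n_members number of members (default 5).
#' @param start,end date span (default 2010-01-01 to 2099-12-31).
#' @return a [climate_ensemble()].
#' @export
gen_projection_members <- function(base_spec, scenario_id,
                                   warming_range, n_members = 5,
                                   start = "2010-01-01", end = "2099-12-31") {
  stopifnot(n_members >= 1, length(warming_range) == 2)
  warmings <- if (n_members == 1) {
    mean(warming_range)
  } else {
    seq(warming_range[1], warming_range[2], length.out = n_members)
  }
  members <- lapply(seq_len(n_members), function(m) {
    sp <- base_spec
    sp$warming_by_2100 <- warmings[m]
    sp$seed <- base_spec$seed + 1000L * m
    cl <- gen_climate(sp, start, end)
    list(model_id = sprintf("pseudo-gcm-%02d", m),
         dates = cl$date, tmean = cl$tmean)
  })
  climate_ensemble(scenario_id, members)
}

#' The true exposure-lag-response surface of the generator
#'
#' Piecewise-linear V-shaped cumulative log relative risk about the MMT:
#' `g(T) = heat_slope * (T - mmt)+ + cold_slope * (mmt - T)+`, distributed
#' over lags 0..`max_lag` by normalised weight profiles (front-loaded for
#' heat, slowly decaying for cold, matching the short heat and multi-week
#' cold lag structure; a negative late-lag heat tail can encode mortality
#' displacement). Because the profiles sum to 1, `g` is exactly the overall
#' cumulative log RR of a sustained temperature.
#'
#' @param mmt minimum-mortality temperature (default 16).
#' @param heat_slope cumulative log RR per degree above the MMT.
#' @param cold_slope cumulative log RR per degree below the MMT.
#' @param heat_lag_profile,cold_lag_profile weights over lags 0..max_lag;
#'   each is normalised to sum to 1. Defaults: heat decays with 2-day mean
#'   lag; cold decays with 10-day mean lag.
#' @param max_lag maximum lag (default 21).
#' @return a `true_surface`.
#' @export
true_surface <- function(mmt = 16, heat_slope = log(1.3) / 10,
                         cold_slope = log(1.4) / 20,
                         heat_lag_profile = NULL, cold_lag_profile = NULL,
                         max_lag = 21L) {
  lags <- 0:max_lag
  if (is.null(heat_lag_profile)) heat_lag_profile <- exp(-lags / 2)
  if (is.null(cold_lag_profile)) cold_lag_profile <- exp(-lags / 10)
  stopifnot(length(heat_lag_profile) == max_lag + 1,
            length(cold_lag_profile) == max_lag + 1,
            sum(heat_lag_profile) != 0, sum(cold_lag_profile) != 0)
  structure(list(mmt = mmt, heat_slope = heat_slope, cold_slope = cold_slope,
                 heat_lag_profile = heat_lag_profile / sum(heat_lag_profile),
                 cold_lag_profile = cold_lag_profile / sum(cold_lag_profile),
                 max_lag = as.integer(max_lag)),
            class = "true_surface")
}

#' True overall cumulative relative risk of a surface
#' @param surface a [true_surface()].
#' @param temps temperatures.
#' @return RR values.
#' @export
true_rr <- function(surface, temps) {
  exp(surface$heat_slope * pmax(temps - surface$mmt, 0) +
        surface$cold_slope * pmax(surface$mmt - temps, 0))
}

# Lag-distributed log-RR contribution for each day; temperatures before the
# series are treated as the MMT (no effect), so callers should prepend a
# burn-in of at least max_lag days.
surface_contribution <- function(surface, tmean) {
  hx <- surface$heat_slope * pmax(tmean - surface$mmt, 0)
  cx <- surface$cold_slope * pmax(surface$mmt - tmean, 0)
  # filter(x, w, sides = 1) gives sum_j w[j] * x[t - j + 1], i.e. weight
  # w[l + 1] on lag l; zero-pad so early days see an MMT (no-effect) history
  lagged_sum <- function(x, w) {
    y <- as.numeric(stats::filter(c(rep(0, surface$max_lag), x),
                                  w, method = "convolution", sides = 1))
    y[(surface$max_lag + 1):length(y)]
  }
  lagged_sum(hx, surface$heat_lag_profile) +
    lagged_sum(cx, surface$cold_lag_profile)
}

#' Generate overdispersed daily death counts
#'
#' `log mu_t = log(baseline_rate) + trend_t + dow_t + lag-distributed
#' surface contribution`; counts are Poisson when `overdispersion = 1` and
#' negative binomial (NB2, variance = overdispersion x mean) otherwise. The
#' trend is a winter-excess cosine of log-amplitude `trend_amplitude` plus a
#' linear secular drift of `secular_per_decade` per 10 years.
#'
#' @param tmean daily temperatures (should include a `max_lag` burn-in; the
#'   first days otherwise assume MMT history).
#' @param dates matching dates (for trend and day-of-week).
#' @param surface a [true_surface()].
#' @param baseline_rate expected deaths/day at reference conditions.
#' @param trend_amplitude log-scale seasonal (non-temperature) amplitude
#'   (default 0.05).
#' @param secular_per_decade log-scale drift per decade (default -0.02).
#' @param dow_effects named log-effects Mon..Sun (default small weekend
#'   deficit).
#' @param overdispersion variance/mean ratio, >= 1 (default 1).
#' @param seed integer seed.
#' @return integer death counts, deterministic given seed.
#' @export
gen_mortality <- function(tmean, dates, surface, baseline_rate = 15,
                          trend_amplitude = 0.05, secular_per_decade = -0.02,
                          dow_effects = default_dow_effects(),
                          overdispersion = 1, seed = 1) {
  n <- length(tmean)
  if (n < 22) stop("series must be at least 22 days")
  stopifnot(length(dates) == n, overdispersion >= 1,
            length(dow_effects) == 7)
  doy <- as.POSIXlt(dates)$yday + 1
  tdays <- as.numeric(dates - dates[1])
  trend <- trend_amplitude * cos(2 * pi * (doy - 15) / 365.25) +
    secular_per_decade * tdays / 3652.5
  wday <- as.POSIXlt(dates)$wday
  dow <- dow_effects[ifelse(wday == 0, 7, wday)]
  eta <- log(baseline_rate) + trend + dow + surface_contribution(surface, tmean)
  mu <- exp(eta)
  set.seed(seed)
  if (overdispersion == 1) {
    stats::rpois(n, mu)
  } else {
    stats::rnbinom(n, mu = mu, size = mu / (overdispersion - 1))
  }
}

#' Default day-of-week log-effects
#'
#' Small weekend registration deficit (Sat -0.02, Sun -0.04), zero otherwise.
#' @return named numeric vector Mon..Sun.
#' @export
default_dow_effects <- function() {
  stats::setNames(c(0, 0, 0, 0, 0, -0.02, -0.04),
                  c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun"))
}

#' Censor small counts for data protection
#'
#' Counts below `threshold` become missing (the data-protection suppression
#' of days with fewer than 3 deaths).
#'
#' @param deaths count vector.
#' @param threshold suppression threshold (default 3); 0 disables.
#' @return counts with values `< threshold` replaced by `NA`.
#' @export
censor_counts <- function(deaths, threshold = 3) {
  stopifnot(threshold >= 0)
  out <- deaths
  out[!is.na(out) & out < threshold] <- NA
  out
}

#' Generate a population trajectory between two endpoints
#'
#' Five-year anchors linearly interpolated between `start_pop` and
#' `end_pop`. Defaults follow the moderate national projection: 5.4 million
#' in 2010 growing to 6.8 million in 2100.
#'
#' @param start_pop,end_pop populations at the endpoint years.
#' @param years `c(first, last)` calendar years (default `c(2010, 2100)`).
#' @param enabled logical, passed through.
#' @return a [population_trajectory()].
#' @export
gen_population <- function(start_pop = 5.4e6, end_pop = 6.8e6,
                           years = c(2010, 2100), enabled = TRUE) {
  stopifnot(start_pop > 0, end_pop > 0, years[2] > years[1])
  anchors <- seq(years[1], years[2], by = 5)
  pop <- start_pop + (end_pop - start_pop) *
    (anchors - years[1]) / (years[2] - years[1])
  population_trajectory(anchors, pop, baseline_year = years[1],
                        enabled = enabled)
}

#' Generate a synthetic daily series for one region
#'
#' Convenience wrapper: climate with a `max_lag` burn-in prepended, mortality
#' from the surface, data-protection censoring, trimmed back to
#' `start..end`.
#'
#' @param region_id region name.
#' @param surface a [true_surface()].
#' @param climate a [climate_gen_spec()].
#' @param start,end observation window.
#' @param baseline_rate deaths/day.
#' @param overdispersion variance/mean ratio.
#' @param censor_threshold suppression threshold (default 3).
#' @param seed integer seed (climate and counts use fixed offsets of it).
#' @param ... passed to [gen_mortality()].
#' @return a [daily_series()].
#' @export
gen_region_series <- function(region_id, surface, climate = climate_gen_spec(),
                              start = "2000-01-01", end = "2017-12-31",
                              baseline_rate = 15, overdispersion = 1.5,
                              censor_threshold = 3, seed = 1, ...) {
  start <- as.Date(start)
  climate$seed <- seed
  cl <- gen_climate(climate, start - surface$max_lag - 1, end)
  deaths <- gen_mortality(cl$tmean, cl$date, surface,
                          baseline_rate = baseline_rate,
                          overdispersion = overdispersion,
                          seed = seed + 500000L, ...)
  keep <- cl$date >= start
  daily_series(region_id, cl$date[keep],
               censor_counts(deaths[keep], censor_threshold),
               cl$tmean[keep])
}

#' Fabricate a complete synthetic study
#'
#' Multi-region observed series (with censoring and the resulting inclusion
#' flags), two pseudo-GCM scenario ensembles, and a population trajectory —
#' every input the pipeline needs, in one call.
#'
#' @param regions data frame with columns `region_id`, `mmt`,
#'   `baseline_rate` (defaults: two regions, a large and a small one whose
#'   counts are mostly suppressed).
#' @param surface a [true_surface()]; its `mmt` is overridden per region.
#' @param n_members ensemble members per scenario (default 5).
#' @param seed integer seed.
#' @return list with `series` (named list of [daily_series()]), `registry`,
#'   `ensembles` (named list of [climate_ensemble()]), `population`,
#'   `surfaces`.
#' @export
make_study <- function(regions = data.frame(
                         region_id = c("Helsinki", "Smallland"),
                         mmt = c(16, 15),
                         baseline_rate = c(15, 1.5)),
                       surface = true_surface(), n_members = 5, seed = 1) {
  series <- list(); surfaces <- list()
  for (i in seq_len(nrow(regions))) {
    surf <- surface
    surf$mmt <- regions$mmt[i]
    surfaces[[regions$region_id[i]]] <- surf
    series[[regions$region_id[i]]] <- gen_region_series(
      regions$region_id[i], surf,
      baseline_rate = regions$baseline_rate[i],
      seed = seed + 17L * i)
  }
  registry <- data.frame(
    region_id = regions$region_id, mmt = regions$mmt,
    missing_fraction = vapply(series, missing_fraction, numeric(1))
  )
  registry <- apply_inclusion_rule(registry)
  ensembles <- list(
    "SSP2-4.5" = gen_projection_members(
      climate_gen_spec(seed = seed + 101L), "SSP2-4.5",
      warming_range = c(2.2, 5.5), n_members = n_members),
    "SSP5-8.5" = gen_projection_members(
      climate_gen_spec(seed = seed + 202L), "SSP5-8.5",
      warming_range = c(5.8, 9.1), n_members = n_members)
  )
  list(series = series, registry = registry, ensembles = ensembles,
       population = gen_population(), surfaces = surfaces)
}
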