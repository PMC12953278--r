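# Future projections: a day-of-year baseline death climatology, population
# scaling, and attribution of each climate-ensemble member's daily
# temperatures, aggregated by decade with pooled uncertainty.

#' Day-of-year baseline death climatology
#'
#' Mean observed deaths per calendar day (suppressed days excluded from the
#' mean); Feb 29 is imputed as the average of the Feb 28 and Mar 1 values.
#' Future baseline death series read this climatology by calendar day.
#'
#' @param series a [daily_series()] with at least two full years.
#' @return named numeric vector of length 366, names `"MM-DD"`.
#' @export
baseline_death_series <- function(series) {
  stopifnot(inherits(series, "daily_series"))
  if (nrow(series) < 2 * 365) stop("need at least two full years")
  key <- mmdd(series$date)
  ok <- !is.na(series$deaths)
  clim <- tapply(series$deaths[ok], key[ok], mean)
  all_days <- mmdd(seq(as.Date("2000-01-01"), as.Date("2000-12-31"), by = 1))
  out <- stats::setNames(rep(NA_real_, 366), all_days)
  out[names(clim)] <- clim
  out["02-29"] <- mean(c(out["02-28"], out["03-01"]))
  if (any(is.na(out))) {
    stop("calendar day with no non-missing observations: ",
         names(out)[which(is.na(out))[1]])
  }
  out
}

#' A population trajectory at five-year anchors
#'
#' @param anchor_years calendar years, ascending, spaced 5 years.
#' @param population persons at each anchor, > 0.
#' @param baseline_year reference year for the scaling factor.
#' @param enabled logical; when `FALSE` the factor is 1 for every year.
#' @return a `population_trajectory`.
#' @export
population_trajectory <- function(anchor_years, population,
                                  baseline_year = anchor_years[1],
                                  enabled = TRUE) {
  stopifnot(length(anchor_years) == length(population),
            all(population > 0), !is.unsorted(anchor_years, strictly = TRUE))
  structure(list(anchor_years = as.numeric(anchor_years),
                 population = as.numeric(population),
                 baseline_year = as.numeric(baseline_year),
                 enabled = isTRUE(enabled)),
            class = "population_trajectory")
}

#' Population scaling factor for a calendar year
#'
#' Linear interpolation of the population between anchors, divided by the
#' population at the baseline year. A disabled trajectory returns 1.
#'
#' @param traj a [population_trajectory()].
#' @param year calendar year(s) within the anchor range.
#' @return multiplier(s).
#' @export
population_factor <- function(traj, year) {
  stopifnot(inherits(traj, "population_trajectory"))
  if (!traj$enabled) return(rep(1, length(year)))
  rng <- range(traj$anchor_years)
  if (any(year < rng[1] | year > rng[2])) {
    stop("year outside the anchor range ", rng[1], "-", rng[2])
  }
  p <- stats::approx(traj$anchor_years, traj$population, xout = year)$y
  p0 <- stats::approx(traj$anchor_years, traj$population,
                      xout = traj$baseline_year)$y
  p / p0
}

#' A climate projection ensemble
#'
#' @param scenario_id scenario label, e.g. `"SSP2-4.5"` or `"SSP5-8.5"`.
#' @param members list of members, each a list with `model_id`, `dates`
#'   (Date), `tmean` (degrees C); all members must share the date axis.
#' @return a `climate_ensemble`.
#' @export
climate_ensemble <- function(scenario_id, members) {
  stopifnot(length(members) >= 1)
  d1 <- members[[1]]$dates
  for (m in members) {
    stopifnot(!is.null(m$model_id), length(m$tmean) == length(m$dates))
    if (!identical(as.integer(m$dates), as.integer(d1))) {
      stop("ensemble members must share the date axis")
    }
  }
  structure(list(scenario_id = scenario_id, members = members),
            class = "climate_ensemble")
}

# Baseline daily deaths for a date axis: climatology by calendar day times
# the population factor of the day's year.
future_deaths <- function(dates, climatology, traj) {
  d <- unname(climatology[mmdd(dates)])
  d * population_factor(traj, date_year(dates))
}

#' Project attributable mortality onto a climate ensemble
#'
#' For each ensemble member the future baseline deaths are the day-of-year
#' climatology scaled by the population factor; daily attribution uses the
#' (adaptation-scaled) overall cumulative curve on the member's temperatures,
#' summed to decades. The point estimate is the across-member mean;
#' uncertainty pools the Monte-Carlo coefficient draws across members, so the
#' empirical 95% interval reflects both coefficient and climate-model spread.
#' Members that do not cover every decade are dropped with a warning.
#'
#' @param curve a `reduced_curve` with fitted covariance.
#' @param ensemble a [climate_ensemble()].
#' @param climatology a [baseline_death_series()] result.
#' @param traj a [population_trajectory()].
#' @param adaptation adaptation fraction or [adaptation_scenario()].
#' @param decades list of ten-year intervals.
#' @param n_draws Monte-Carlo draws per member.
#' @param seed integer seed.
#' @return data frame `decade`, `component`, `an`, `af`, `lo95`, `hi95` with
#'   attributes `scenario_id`, `n_members`, `n_mc`, `seed`.
#' @export
project_scenario <- function(curve, ensemble, climatology, traj,
                             adaptation = 0, decades = default_decades(),
                             n_draws = 500, seed = 1) {
  stopifnot(inherits(curve, "reduced_curve"),
            inherits(ensemble, "climate_ensemble"))
  check_decades(decades)
  dates <- ensemble$members[[1]]$dates
  yrs <- date_year(dates)
  covered <- vapply(decades, function(d) {
    ndays <- sum(yrs >= d[1] & yrs <= d[2])
    ndays >= 10 * 365
  }, logical(1))
  if (!all(covered)) {
    bad <- which(!covered)
    stop("ensemble does not cover decade(s): ",
         paste(vapply(decades[bad], decade_label, character(1)),
               collapse = ", "))
  }
  deaths <- future_deaths(dates, climatology, traj)
  nd <- length(decades)
  comp <- c("heat", "cold", "total")
  members <- ensemble$members

  point <- array(0, dim = c(length(members), nd, 3))
  dsum <- rep(0, nd)
  idx <- decade_index(dates, decades)
  for (i in seq_len(nd)) dsum[i] <- sum(deaths[!is.na(idx) & idx == i])
  for (m in seq_along(members)) {
    da <- daily_attributable(deaths, members[[m]]$tmean, curve, adaptation)
    tot <- decade_totals(dates, deaths, da$an, da$component, decades)
    point[m, , ] <- tot[, comp]
  }
  an_point <- apply(point, c(2, 3), mean)

  set.seed(seed)
  draws <- rmvn(n_draws, curve$coef, curve$vcov)
  pooled <- vector("list", length(members))
  for (m in seq_along(members)) {
    pooled[[m]] <- mc_decade_an(curve, deaths, members[[m]]$tmean, dates,
                                decades, draws, adaptation)
  }
  sims <- do.call(abind1, pooled)   # [member*draw, decade, component]
  qs <- apply(sims, c(2, 3), stats::quantile, probs = c(0.025, 0.975),
              type = 7)
  out <- data.frame(
    decade = rep(vapply(decades, decade_label, character(1)), each = 3),
    component = rep(comp, nd),
    an = as.numeric(t(an_point)),
    af = as.numeric(t(an_point / dsum * 100)),
    lo95 = as.numeric(t(qs[1, , comp])),
    hi95 = as.numeric(t(qs[2, , comp]))
  )
  attr(out, "scenario_id") <- ensemble$scenario_id
  attr(out, "n_members") <- length(members)
  attr(out, "n_mc") <- n_draws
  attr(out, "seed") <- seed
  out
}

# Bind arrays along the first dimension.
abind1 <- function(...) {
  xs <- list(...)
  d <- dim(xs[[1]])
  out <- array(0, dim = c(sum(vapply(xs, function(x) dim(x)[1], numeric(1))),
                          d[2], d[3]),
               dimnames = c(list(NULL), dimnames(xs[[1]])[2:3]))
  at <- 0
  for (x in xs) {
    out[at + seq_len(dim(x)[1]), , ] <- x
    at <- at + dim(x)[1]
  }
  out
}
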