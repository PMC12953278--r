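# Attributable mortality: per-day attributable deaths
# AN_t = D_t * (1 - exp(-logRR(T_t))), split into heat (T > MMT) and cold
# (T < MMT), aggregated to closed ten-year intervals as attributable numbers
# (AN) and fractions (AF, % of total deaths), with Monte-Carlo empirical
# confidence intervals from multivariate-normal draws of the reduced-curve
# coefficients.

adaptation_fraction <- function(adaptation) {
  if (inherits(adaptation, "adaptation_scenario")) {
    adaptation$fraction
  } else {
    adaptation_scenario(adaptation)$fraction
  }
}

# Centred adapted log RR from a precomputed centred basis.
logrr_from_basis <- function(Xc, coef, heat, frac) {
  logrr <- drop(Xc %*% coef)
  if (frac > 0) {
    logrr[heat] <- log(1 + (1 - frac) * (exp(logrr[heat]) - 1))
  }
  logrr
}

# Centred adapted log RR for a temperature vector under given coefficients.
adapted_logrr <- function(curve, tmean, coef, adaptation = 0) {
  logrr_from_basis(centred_basis(curve, tmean), coef, tmean > curve$mmt,
                   adaptation_fraction(adaptation))
}

#' Daily temperature-attributable deaths
#'
#' For each day, the deaths attributable to non-optimal temperature:
#' `AN_t = D_t * (1 - exp(-logRR(T_t)))`, where the log relative risk is the
#' overall cumulative curve centred at the MMT (with any adaptation scaling
#' applied to the heat side). Days are labelled `heat` when the temperature
#' exceeds the MMT, `cold` below it, `none` at it. Negative AN is legitimate
#' where the fitted curve dips below RR = 1.
#'
#' @param deaths daily death counts (observed or projected baseline);
#'   non-negative, `NA` allowed.
#' @param tmean daily mean temperatures (degrees C).
#' @param curve a [reduce_overall()] / [reduced_curve()] result.
#' @param adaptation an [adaptation_scenario()] or fraction in `[0, 1]`.
#' @return data frame with `an` and `component`.
#' @export
daily_attributable <- function(deaths, tmean, curve, adaptation = 0) {
  stopifnot(inherits(curve, "reduced_curve"),
            length(deaths) == length(tmean))
  if (any(deaths < 0, na.rm = TRUE)) stop("negative deaths")
  logrr <- adapted_logrr(curve, tmean, curve$coef, adaptation)
  an <- deaths * (1 - exp(-logrr))
  component <- ifelse(tmean > curve$mmt, "heat",
                      ifelse(tmean < curve$mmt, "cold", "none"))
  data.frame(an = an, component = component)
}

# Decade index of each date (NA outside all decades).
decade_index <- function(dates, decades) {
  yr <- date_year(dates)
  idx <- rep(NA_integer_, length(dates))
  for (i in seq_along(decades)) {
    d <- decades[[i]]
    idx[yr >= d[1] & yr <= d[2]] <- i
  }
  idx
}

# Sum per-day AN into decade x component totals plus the decade's total
# deaths. Returns a matrix [decade, c(heat, cold, total, deaths)].
decade_totals <- function(dates, deaths, an, component, decades) {
  idx <- decade_index(dates, decades)
  keep <- !is.na(idx) & !is.na(an)
  nd <- length(decades)
  out <- matrix(0, nd, 4, dimnames = list(
    vapply(decades, decade_label, character(1)),
    c("heat", "cold", "total", "deaths")))
  heat <- component == "heat"
  cold <- component == "cold"
  for (i in seq_len(nd)) {
    s <- keep & idx == i
    out[i, "heat"] <- sum(an[s & heat])
    out[i, "cold"] <- sum(an[s & cold])
    out[i, "total"] <- sum(an[s])
    out[i, "deaths"] <- sum(deaths[!is.na(idx) & idx == i], na.rm = TRUE)
  }
  out
}

#' Aggregate daily attributable deaths to decades
#'
#' Sums attributable deaths within each closed ten-year interval and reports
#' attributable fractions `AF = 100 * AN / sum(deaths)` over the same days,
#' for the heat, cold and total components.
#'
#' @param dates daily dates.
#' @param deaths daily death counts.
#' @param daily output of [daily_attributable()] for those days.
#' @param decades list of `c(start_year, end_year)` ten-year intervals.
#' @return data frame with `decade`, `component`, `an`, `af`.
#' @export
aggregate_decades <- function(dates, deaths, daily, decades) {
  check_decades(decades)
  tot <- decade_totals(dates, deaths, daily$an, daily$component, decades)
  if (any(tot[, "deaths"] <= 0)) {
    stop("decade with zero total deaths: attributable fraction undefined")
  }
  comp <- c("heat", "cold", "total")
  data.frame(
    decade = rep(rownames(tot), each = length(comp)),
    component = rep(comp, nrow(tot)),
    an = as.numeric(t(tot[, comp, drop = FALSE])),
    af = as.numeric(t(tot[, comp, drop = FALSE] / tot[, "deaths"] * 100))
  )
}

#' End-of-century to baseline change ratio
#'
#' Ratio of a future to a baseline attributable number, rounded
#' half-away-from-zero to one decimal. Computed from unrounded inputs;
#' undefined (reported `NA`, printed "-") when the baseline is zero or
#' negative.
#'
#' @param an_future future-period attributable number.
#' @param an_baseline baseline-period attributable number.
#' @return ratio rounded to 1 decimal, or `NA` where undefined.
#' @export
change_ratio <- function(an_future, an_baseline) {
  out <- ifelse(an_baseline > 0, an_future / an_baseline, NA_real_)
  round_half_away(out, 1)
}

#' Monte-Carlo confidence intervals for decade attributable numbers
#'
#' Draws reduced-curve coefficients from a multivariate normal with the
#' fitted mean and covariance, recomputes every decade's heat/cold/total AN
#' per draw, and reports empirical 2.5th/97.5th percentiles (linear
#' interpolation). One RNG stream, governed by `seed`, is shared across
#' decades so draws are coherent in time.
#'
#' @param curve a `reduced_curve` with its fitted covariance.
#' @param deaths,tmean,dates daily series the attribution runs on.
#' @param decades list of ten-year intervals.
#' @param n_draws number of draws (>= 100).
#' @param seed integer seed.
#' @param adaptation adaptation fraction or [adaptation_scenario()].
#' @return data frame with `decade`, `component`, `an`, `af`, `lo95`, `hi95`;
#'   attributes `n_mc` and `seed`.
#' @export
montecarlo_ci <- function(curve, deaths, tmean, dates, decades,
                          n_draws = 1000, seed = 1, adaptation = 0) {
  stopifnot(inherits(curve, "reduced_curve"), n_draws >= 100)
  check_decades(decades)
  point <- aggregate_decades(
    dates, deaths,
    daily_attributable(deaths, tmean, curve, adaptation), decades)
  set.seed(seed)
  draws <- rmvn(n_draws, curve$coef, curve$vcov)
  sims <- mc_decade_an(curve, deaths, tmean, dates, decades, draws, adaptation)
  qs <- apply(sims, c(2, 3), stats::quantile, probs = c(0.025, 0.975),
              type = 7)
  comp <- c("heat", "cold", "total")
  lo <- as.numeric(t(qs[1, , comp]))
  hi <- as.numeric(t(qs[2, , comp]))
  out <- cbind(point, lo95 = lo, hi95 = hi)
  attr(out, "n_mc") <- n_draws
  attr(out, "seed") <- seed
  out
}

# Decade AN per coefficient draw: array [draw, decade, component].
mc_decade_an <- function(curve, deaths, tmean, dates, decades, draws,
                         adaptation = 0) {
  idx <- decade_index(dates, decades)
  component <- ifelse(tmean > curve$mmt, "heat",
                      ifelse(tmean < curve$mmt, "cold", "none"))
  nd <- length(decades)
  sims <- array(0, dim = c(nrow(draws), nd, 3),
                dimnames = list(NULL, vapply(decades, decade_label,
                                             character(1)),
                                c("heat", "cold", "total")))
  heat <- component == "heat"
  Xc <- centred_basis(curve, tmean)
  frac <- adaptation_fraction(adaptation)
  ok <- !is.na(idx) & !is.na(deaths)
  # group index: decade x {heat, cold} for fast rowsum aggregation
  grp <- ifelse(heat, 2 * idx - 1, 2 * idx)
  grp[component == "none"] <- NA
  for (k in seq_len(nrow(draws))) {
    logrr <- logrr_from_basis(Xc, draws[k, ], heat, frac)
    an <- deaths * (1 - exp(-logrr))
    keep <- ok & !is.na(grp)
    sums <- rowsum(an[keep], grp[keep])
    lab <- as.integer(rownames(sums))
    for (i in seq_len(nd)) {
      h <- sums[match(2 * i - 1, lab), 1]
      cd <- sums[match(2 * i, lab), 1]
      sims[k, i, "heat"] <- if (is.na(h)) 0 else h
      sims[k, i, "cold"] <- if (is.na(cd)) 0 else cd
      sims[k, i, "total"] <- sims[k, i, "heat"] + sims[k, i, "cold"]
    }
  }
  sims
}
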