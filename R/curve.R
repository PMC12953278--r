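# Reduction of the fitted exposure-lag surface to the overall cumulative
# exposure-response curve (lag-summed relative risk), centred at the
# minimum-mortality temperature (MMT), and the adaptation transform applied
# to the heat side of the curve.

#' Reduce a fitted DLNM to the overall cumulative curve
#'
#' Sums the lag-basis contributions over lags `0..max_lag`: with cross-basis
#' coefficients `theta` (exposure-major ordering) the reduced exposure-basis
#' coefficients are `M theta` and their covariance `M V M'`, where row `i` of
#' `M` carries the column sums of the lag basis in block `i`. The resulting
#' curve gives the log relative risk of a sustained temperature relative to
#' the MMT, accumulated over the full lag window.
#'
#' @param fit a [fit_quasipoisson()] result whose `cb_cols` index the
#'   cross-basis block.
#' @param cbspec the [crossbasis_spec()] used to build that block.
#' @param mmt minimum-mortality temperature (degrees C), the reference at
#'   which RR = 1.
#' @return a `reduced_curve`: `coef` (length vx), `vcov` (vx x vx),
#'   `var_spec`, `mmt`.
#' @export
reduce_overall <- function(fit, cbspec, mmt) {
  stopifnot(inherits(fit, "fitted_dlnm"), inherits(cbspec, "crossbasis_spec"))
  vx <- spec_df(cbspec$var_spec)
  vl <- spec_df(cbspec$lag_spec)
  if (length(fit$cb_cols) != vx * vl) {
    stop("cross-basis block in fit does not match the specification")
  }
  labs <- fit$design_labels[fit$cb_cols]
  expect <- paste0("cb_v", rep(seq_len(vx), each = vl),
                   "_l", rep(seq_len(vl), vx))
  if (!identical(labs, expect)) {
    stop("cross-basis column labels do not match the specification")
  }
  csum <- colSums(ns_basis(0:cbspec$max_lag, cbspec$lag_spec))
  M <- matrix(0, vx, vx * vl)
  for (i in seq_len(vx)) M[i, (i - 1L) * vl + seq_len(vl)] <- csum
  theta <- fit$coefficients[fit$cb_cols]
  V <- fit$vcov[fit$cb_cols, fit$cb_cols, drop = FALSE]
  structure(list(coef = drop(M %*% theta), vcov = M %*% V %*% t(M),
                 var_spec = cbspec$var_spec, mmt = as.numeric(mmt)),
            class = "reduced_curve")
}

#' Construct a reduced curve directly from coefficients
#'
#' Mainly for tests and synthetic work: wraps exposure-basis coefficients and
#' covariance as a curve centred at `mmt`.
#'
#' @param coef exposure-basis coefficients (length `spec_df(var_spec)`).
#' @param vcov covariance matrix (use a zero matrix for a deterministic
#'   curve).
#' @param var_spec the exposure [spline_spec()].
#' @param mmt reference temperature.
#' @return a `reduced_curve`.
#' @export
reduced_curve <- function(coef, vcov, var_spec, mmt) {
  vx <- spec_df(var_spec)
  stopifnot(length(coef) == vx, all(dim(vcov) == c(vx, vx)))
  structure(list(coef = as.numeric(coef), vcov = vcov,
                 var_spec = var_spec, mmt = as.numeric(mmt)),
            class = "reduced_curve")
}

# Centred contrast basis: b(T) - b(mmt), one row per temperature. Centring at
# the MMT makes log RR(mmt) = 0 with zero variance by construction, and is
# idempotent: the contrast of a contrast at mmt is unchanged.
centred_basis <- function(curve, temps) {
  B <- ns_basis(temps, curve$var_spec)
  b0 <- ns_basis(curve$mmt, curve$var_spec)
  sweep(B, 2, drop(b0), "-")
}

#' Predict relative risk along a temperature grid
#'
#' log RR(T) = (b(T) - b(mmt))' coef with Wald 95% confidence limits on the
#' log scale; at the MMT the RR is exactly 1 with a degenerate interval.
#'
#' @param curve a [reduce_overall()] / [reduced_curve()] result.
#' @param temps temperature grid (degrees C).
#' @return data frame with `temp`, `rr`, `lo95`, `hi95`.
#' @export
predict_rr <- function(curve, temps) {
  stopifnot(inherits(curve, "reduced_curve"))
  if (length(temps) == 0) stop("empty temperature grid")
  Xc <- centred_basis(curve, temps)
  logrr <- drop(Xc %*% curve$coef)
  se <- sqrt(pmax(rowSums((Xc %*% curve$vcov) * Xc), 0))
  z <- stats::qnorm(0.975)
  data.frame(temp = temps, rr = exp(logrr),
             lo95 = exp(logrr - z * se), hi95 = exp(logrr + z * se))
}

#' An adaptation scenario
#'
#' A stipulated proportional reduction of the heat-side excess relative risk:
#' under adaptation fraction `a`, a heat RR becomes `1 + (1 - a) * (RR - 1)`.
#' The cold side is untouched. Scaling the excess (rather than the RR or log
#' RR) keeps an adapted heat RR above 1 and makes `a = 1` remove the heat
#' burden exactly.
#'
#' @param fraction adaptation fraction in `[0, 1]` (0 = none, 0.2 and 0.5 are
#'   the conventional low/high scenarios).
#' @return an `adaptation_scenario`.
#' @export
adaptation_scenario <- function(fraction = 0) {
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      fraction < 0 || fraction > 1) {
    stop("adaptation fraction must be in [0, 1]")
  }
  structure(list(fraction = fraction), class = "adaptation_scenario")
}

#' Apply adaptation scaling to relative risks
#'
#' @param rr_value relative risk(s), > 0.
#' @param scenario an [adaptation_scenario()] (or a bare fraction).
#' @param is_heat logical vector: `TRUE` where the temperature is above the
#'   MMT (only those entries are scaled).
#' @return adapted relative risks.
#' @export
apply_adaptation <- function(rr_value, scenario, is_heat) {
  if (!inherits(scenario, "adaptation_scenario")) {
    scenario <- adaptation_scenario(scenario)
  }
  if (any(rr_value <= 0)) stop("relative risk must be positive")
  a <- scenario$fraction
  out <- rr_value
  out[is_heat] <- 1 + (1 - a) * (rr_value[is_heat] - 1)
  out
}

#' Export a curve as a plotting table
#'
#' @param curve a `reduced_curve`.
#' @param path output CSV path.
#' @param temps temperature grid; defaults to 150 points across the basis
#'   boundary range.
#' @return the prediction data frame, invisibly.
#' @export
write_curve <- function(curve, path, temps = NULL) {
  if (is.null(temps)) {
    b <- curve$var_spec$boundary_knots
    temps <- seq(b[1], b[2], length.out = 150)
  }
  pred <- predict_rr(curve, temps)
  utils::write.csv(pred, path, row.names = FALSE)
  invisible(pred)
}
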