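# Quasi-Poisson DLNM fitting: log E[Y_t] = alpha + crossbasis(T, lag) +
# long-term/seasonal trend spline + day-of-week indicators. Dispersion is the
# Pearson estimate; model selection across knot specifications uses qAIC.

#' Assemble the regression design for a daily series
#'
#' Columns: intercept, the cross-basis block, a natural cubic spline of the
#' day index with `round(trend_df_per_year * years)` degrees of freedom
#' (long-term and seasonal trend), and six day-of-week indicators (Monday
#' reference). Rows with a missing (suppressed) death count or an incomplete
#' lag window are masked out of the likelihood; their temperatures still feed
#' the lag windows of later days.
#'
#' @param series a [daily_series()].
#' @param cb a [build_crossbasis()] result aligned with `series`.
#' @param trend_df_per_year trend degrees of freedom per year (default 7).
#' @return list with `X` (design matrix), `y` (deaths), `mask` (usable rows),
#'   `cb_cols` (indices of the cross-basis block), `dates`.
#' @export
build_design <- function(series, cb, trend_df_per_year = 7) {
  stopifnot(inherits(series, "daily_series"), inherits(cb, "crossbasis"))
  n <- nrow(series)
  if (nrow(cb$matrix) != n) stop("series and cross-basis are not aligned")
  years <- n / 365.25
  trend_df <- max(2L, as.integer(round(trend_df_per_year * years)))
  trend <- splines::ns(seq_len(n), df = trend_df)
  wday <- as.POSIXlt(series$date)$wday        # 0 = Sunday
  dow <- factor(wday, levels = c(1:6, 0),
                labels = c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun"))
  dow_ind <- stats::model.matrix(~dow)[, -1, drop = FALSE]
  X <- cbind(`(Intercept)` = 1, cb$matrix, trend, dow_ind)
  ncb <- ncol(cb$matrix)
  colnames(X) <- c("(Intercept)", colnames(cb$matrix),
                   paste0("trend", seq_len(ncol(trend))), colnames(dow_ind))
  mask <- !is.na(series$deaths) & seq_len(n) >= cb$valid_from
  if (!any(mask)) stop("all rows masked: no usable observations")
  list(X = X, y = series$deaths, mask = mask,
       cb_cols = 1L + seq_len(ncb), dates = series$date)
}

#' Fit a quasi-Poisson regression
#'
#' Maximises the Poisson log-likelihood by iteratively reweighted least
#' squares (relative deviance change below 1e-10, at most 100 iterations),
#' then estimates overdispersion by the Pearson statistic
#' `sum((y - mu)^2 / mu) / (n - p)` and scales the inverse Fisher information
#' by it to give the coefficient covariance.
#'
#' @param design output of [build_design()] (or a list with `X`, `y`, `mask`,
#'   optionally `cb_cols`).
#' @return a `fitted_dlnm` object: coefficients, covariance, dispersion,
#'   Poisson log-likelihood, `n_used`, `cb_cols`, `design_labels`.
#' @export
fit_quasipoisson <- function(design) {
  X <- design$X[design$mask, , drop = FALSE]
  y <- design$y[design$mask]
  if (any(y < 0)) stop("negative response")
  p <- ncol(X)
  qrX <- qr(X)
  if (qrX$rank < p) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):p]]
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  fit <- stats::glm.fit(X, y, family = stats::poisson(),
                        control = stats::glm.control(epsilon = 1e-10,
                                                     maxit = 100))
  if (!fit$converged) {
    stop("IRLS did not converge in 100 iterations; deviance ", fit$deviance)
  }
  mu <- fit$fitted.values
  n <- length(y)
  dispersion <- sum((y - mu)^2 / mu) / (n - p)
  # inverse Fisher information at the fit, scaled by the dispersion
  XtWX <- crossprod(X * sqrt(mu))
  vcov <- dispersion * chol2inv(chol(XtWX))
  dimnames(vcov) <- list(colnames(X), colnames(X))
  structure(
    list(coefficients = stats::setNames(fit$coefficients, colnames(X)),
         vcov = vcov, dispersion = dispersion,
         loglik = sum(stats::dpois(y, mu, log = TRUE)),
         n_used = n, fitted = mu, y = y,
         cb_cols = design$cb_cols, design_labels = colnames(X)),
    class = "fitted_dlnm"
  )
}

#' @export
print.fitted_dlnm <- function(x, ...) {
  cat("Quasi-Poisson DLNM fit:", length(x$coefficients), "coefficients,",
      x$n_used, "days\n")
  cat(sprintf("  dispersion %.3f, qAIC %.1f\n", x$dispersion, qaic(x)))
  invisible(x)
}

#' Quasi-Akaike information criterion
#'
#' `qAIC = -2 * loglik + 2 * p * dispersion`: the usual AIC with the
#' parameter penalty inflated by the estimated overdispersion, so that at
#' dispersion 1 it reduces to ordinary AIC.
#'
#' @param fit a [fit_quasipoisson()] result.
#' @return qAIC value.
#' @export
qaic <- function(fit) {
  stopifnot(inherits(fit, "fitted_dlnm"))
  -2 * fit$loglik + 2 * length(fit$coefficients) * fit$dispersion
}

#' A knot-specification candidate for model selection
#'
#' @param var_percentiles exposure knot percentiles.
#' @param n_lag_knots number of internal lag knots (equally spaced on
#'   `0..max_lag`).
#' @return a `knot_candidate` list.
#' @export
knot_candidate <- function(var_percentiles, n_lag_knots) {
  structure(list(var_percentiles = as.numeric(var_percentiles),
                 n_lag_knots = as.integer(n_lag_knots)),
            class = "knot_candidate")
}

#' Default candidate grid for qAIC knot selection
#'
#' Exposure knots at {(10,75,90), (10,50,90), (25,50,75), (33,66), (50)}
#' percentiles crossed with 1-3 internal lag knots equally spaced on the lag
#' scale.
#'
#' @return list of [knot_candidate()]s.
#' @export
default_candidates <- function() {
  var_sets <- list(c(10, 75, 90), c(10, 50, 90), c(25, 50, 75),
                   c(33, 66), 50)
  out <- list()
  for (v in var_sets) for (k in 1:3) out <- c(out, list(knot_candidate(v, k)))
  out
}

# Total df of a candidate's cross-basis block.
candidate_df <- function(cand, max_lag = 21L) {
  (length(cand$var_percentiles) + 1L) * (cand$n_lag_knots + 2L)
}

#' Select a knot specification by qAIC
#'
#' Fits every candidate to the series and returns the one with minimal qAIC.
#' Ties (to machine precision) go to the candidate with fewer cross-basis
#' degrees of freedom, then to the fixed-knots default (10/75/90 exposure
#' percentiles, 2 lag knots) if it is among the tied set. Candidates that
#' fail to fit are skipped with a warning.
#'
#' @param series a [daily_series()].
#' @param candidates list of [knot_candidate()]s.
#' @param max_lag maximum lag (default 21).
#' @param trend_df_per_year trend df per year (default 7).
#' @return the selected [knot_candidate()] with element `qaic` filled in.
#' @export
select_spec <- function(series, candidates = default_candidates(),
                        max_lag = 21L, trend_df_per_year = 7) {
  stopifnot(length(candidates) >= 1)
  scores <- rep(NA_real_, length(candidates))
  for (i in seq_along(candidates)) {
    cand <- candidates[[i]]
    scores[i] <- tryCatch({
      spec <- default_crossbasis_spec(series$tmean, cand$var_percentiles,
                                      cand$n_lag_knots, max_lag)
      cb <- build_crossbasis(series$tmean, spec)
      fit <- fit_quasipoisson(build_design(series, cb, trend_df_per_year))
      qaic(fit)
    }, error = function(e) {
      warning("candidate ", i, " failed to fit: ", conditionMessage(e))
      NA_real_
    })
  }
  if (all(is.na(scores))) stop("no candidate could be fitted")
  tol <- 1e-8 * max(1, abs(min(scores, na.rm = TRUE)))
  tied <- which(!is.na(scores) & scores <= min(scores, na.rm = TRUE) + tol)
  if (length(tied) > 1) {
    dfs <- vapply(candidates[tied], candidate_df, numeric(1), max_lag)
    tied <- tied[dfs == min(dfs)]
    if (length(tied) > 1) {
      is_default <- vapply(candidates[tied], function(cand) {
        identical(cand$var_percentiles, c(10, 75, 90)) &&
          cand$n_lag_knots == 2L
      }, logical(1))
      if (any(is_default)) tied <- tied[is_default]
    }
  }
  best <- candidates[[tied[1]]]
  best$qaic <- scores[tied[1]]
  best
}
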