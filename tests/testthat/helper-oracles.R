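# Independent oracles used across the suite. These deliberately do not call
# the package's own construction paths.

# Natural cubic spline basis from the truncated-power representation with the
# linearity (zero second derivative) constraints beyond the outer knots
# imposed directly: N1 = 1, N2 = x, N_{k+2} = d_k - d_{K-1} with
# d_k(x) = [(x - k_k)_+^3 - (x - k_K)_+^3] / (k_K - k_k), over the full knot
# sequence (boundary + internal). Spans the natural cubic spline space.
ns_tp_basis <- function(x, knots_all) {
  K <- length(knots_all)
  stopifnot(K >= 2, !is.unsorted(knots_all, strictly = TRUE))
  pp3 <- function(u) pmax(u, 0)^3
  d <- function(k) {
    (pp3(x - knots_all[k]) - pp3(x - knots_all[K])) /
      (knots_all[K] - knots_all[k])
  }
  out <- cbind(1, x)
  if (K > 2) {
    for (k in seq_len(K - 2)) out <- cbind(out, d(k) - d(K - 1))
  }
  out
}

# Largest residual of projecting columns of A onto the column space of B.
span_residual <- function(A, B) {
  max(abs(qr.resid(qr(B), A)))
}

# Hand-rolled Poisson IRLS (log link), iterated to the same tolerance as the
# package fit.
irls_oracle <- function(X, y, tol = 1e-12, maxit = 200) {
  b <- c(log(mean(y) + 0.5), rep(0, ncol(X) - 1))
  dev_old <- Inf
  for (i in seq_len(maxit)) {
    eta <- drop(X %*% b)
    mu <- exp(eta)
    z <- eta + (y - mu) / mu
    b <- solve(crossprod(X * sqrt(mu)), crossprod(X * mu, z))
    dev <- -2 * sum(stats::dpois(y, exp(drop(X %*% b)), log = TRUE))
    if (abs(dev - dev_old) / (abs(dev) + 0.1) < tol) break
    dev_old <- dev
  }
  drop(b)
}

# Day-by-day attributable-death loop: the naive re-implementation of the
# attribution formula, one day at a time, with its own centred-spline
# evaluation per day.
attribution_loop_oracle <- function(deaths, tmean, curve, adaptation = 0) {
  an <- numeric(length(deaths))
  comp <- character(length(deaths))
  for (t in seq_along(deaths)) {
    bT <- ns_basis(tmean[t], curve$var_spec)
    b0 <- ns_basis(curve$mmt, curve$var_spec)
    logrr <- sum((bT - b0) * curve$coef)
    rr <- exp(logrr)
    if (tmean[t] > curve$mmt) {
      rr <- 1 + (1 - adaptation) * (rr - 1)
      comp[t] <- "heat"
    } else if (tmean[t] < curve$mmt) {
      comp[t] <- "cold"
    } else {
      comp[t] <- "none"
    }
    an[t] <- deaths[t] * (1 - 1 / rr)
  }
  data.frame(an = an, component = comp)
}

# Cross-basis entry by explicit loop over lags (zero history before the
# window, matching valid_from masking which drops those rows anyway).
crossbasis_loop_oracle <- function(tmean, spec) {
  L <- spec$max_lag
  vx <- spec_df(spec$var_spec)
  vl <- spec_df(spec$lag_spec)
  Cl <- ns_basis(0:L, spec$lag_spec)
  n <- length(tmean)
  M <- matrix(NA_real_, n, vx * vl)
  for (t in (L + 1):n) {
    Bt <- ns_basis(tmean[t - (0:L)], spec$var_spec)  # (L+1) x vx
    for (i in seq_len(vx)) {
      for (j in seq_len(vl)) {
        M[t, (i - 1) * vl + j] <- sum(Bt[, i] * Cl[, j])
      }
    }
  }
  M
}

# A small fitted series shared by several tests: 3 years, moderate effects.
make_test_series <- function(seed = 7, years = 3, rate = 15,
                             surface = true_surface(mmt = 16),
                             overdispersion = 1.3) {
  gen_region_series("Testland", surface,
                    start = "2000-01-01",
                    end = sprintf("%d-12-31", 1999 + years),
                    baseline_rate = rate, overdispersion = overdispersion,
                    censor_threshold = 0, seed = seed)
}

# A deterministic log-linear heat curve: zero-knot (linear) exposure basis
# with coefficient chosen so log RR rises by `slope` per degree above the
# reference; useful for closed-form attribution checks.
make_linear_curve <- function(slope = log(1.2) / 10, mmt = 16,
                              range = c(-20, 30), vcov0 = TRUE) {
  vs <- spline_spec(numeric(0), range, intercept = FALSE)
  col_slope <- diff(drop(ns_basis(c(0, 1), vs)))
  v <- if (vcov0) matrix(0, 1, 1) else matrix((slope / col_slope)^2 * 0.01, 1, 1)
  reduced_curve(slope / col_slope, v, vs, mmt)
}
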