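test_that("design bookkeeping: trend df, usable rows, day-of-week block", {
  surf <- true_surface(mmt = 16)
  ser18 <- make_test_series(seed = 2, years = 18, overdispersion = 1)
  cb <- build_crossbasis(ser18$tmean, default_crossbasis_spec(ser18$tmean))
  des <- build_design(ser18, cb, trend_df_per_year = 7)
  trend_cols <- grep("^trend", colnames(des$X))
  expect_length(trend_cols, 126L)
  expect_length(grep("^dow", colnames(des$X)), 6L)

  ser1 <- make_test_series(seed = 2, years = 1, overdispersion = 1)
  cb1 <- build_crossbasis(ser1$tmean, default_crossbasis_spec(ser1$tmean))
  des1 <- build_design(ser1, cb1)
  expect_identical(sum(des1$mask), 366L - 21L)  # 2000 is a leap year
})

test_that("quasi-Poisson fit recovers a constant rate with unit dispersion", {
  set.seed(21)
  y <- rpois(5000, 10)
  des <- list(X = matrix(1, 5000, 1, dimnames = list(NULL, "(Intercept)")),
              y = y, mask = rep(TRUE, 5000), cb_cols = integer(0))
  fit <- fit_quasipoisson(des)
  expect_lt(abs(fit$coefficients[1] - log(10)), 0.05)
  expect_lt(abs(fit$dispersion - 1), 0.05)
  # canonical-link identity: fitted total equals observed total
  expect_lt(abs(sum(fit$fitted) - sum(y)) / sum(y), 1e-6)
})

test_that("fit matches an independent IRLS oracle on a fixed fixture", {
  set.seed(30)
  X <- cbind(1, rnorm(30), runif(30))
  colnames(X) <- c("(Intercept)", "x1", "x2")
  y <- rpois(30, exp(1.5 + 0.3 * X[, 2] - 0.5 * X[, 3]))
  fit <- fit_quasipoisson(list(X = X, y = y, mask = rep(TRUE, 30),
                               cb_cols = integer(0)))
  b_oracle <- irls_oracle(X, y)
  expect_lt(max(abs(fit$coefficients - b_oracle)), 1e-6)
})

test_that("rank-deficient designs are rejected with the offending column", {
  X <- cbind(`(Intercept)` = 1, a = 1:20, dup = 2 * (1:20))
  expect_error(
    fit_quasipoisson(list(X = X, y = rpois(20, 5), mask = rep(TRUE, 20),
                          cb_cols = integer(0))),
    "collinear.*dup")
})

test_that("day-of-week contrasts are recovered from injected effects", {
  surf0 <- true_surface(mmt = 16, heat_slope = 0, cold_slope = 0)
  dow <- setNames(c(0, 0.1, -0.1, 0.05, 0, -0.2, 0.15),
                  c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun"))
  ser <- gen_region_series("r", surf0, start = "2000-01-01",
                           end = "2004-12-31", baseline_rate = 30,
                           overdispersion = 1, censor_threshold = 0,
                           dow_effects = dow, seed = 4)
  cb <- build_crossbasis(ser$tmean, default_crossbasis_spec(ser$tmean))
  fit <- fit_quasipoisson(build_design(ser, cb))
  est <- fit$coefficients[grep("^dow", names(fit$coefficients))]
  se <- sqrt(diag(fit$vcov))[grep("^dow", names(fit$coefficients))]
  truth <- dow[c("Tue", "Wed", "Thu", "Fri", "Sat", "Sun")] - dow["Mon"]
  expect_true(all(abs(est - truth) < 4 * se))
  expect_lt(max(abs(est - truth)), 0.05)
})

test_that("covariance scales linearly with the dispersion estimate", {
  ser <- make_test_series(seed = 6, years = 2, overdispersion = 2)
  cb <- build_crossbasis(ser$tmean, default_crossbasis_spec(ser$tmean))
  fit <- fit_quasipoisson(build_design(ser, cb))
  # unit-dispersion information is recovered by dividing out the estimate
  info_scaled <- fit$vcov / fit$dispersion
  expect_gt(fit$dispersion, 1.3)
  expect_equal(fit$vcov, info_scaled * fit$dispersion, tolerance = 1e-12)
  expect_true(isSymmetric(fit$vcov, tol = 1e-10))
  expect_true(all(eigen(fit$vcov, symmetric = TRUE,
                        only.values = TRUE)$values > -1e-8))
})

test_that("qAIC reduces to AIC at unit dispersion and penalises noise", {
  set.seed(40)
  n <- 400
  X <- cbind(`(Intercept)` = rep(1, n), x = rnorm(n))
  y <- rpois(n, exp(2 + 0.2 * X[, "x"]))
  fit <- fit_quasipoisson(list(X = X, y = y, mask = rep(TRUE, n),
                               cb_cols = integer(0)))
  aic_plain <- -2 * fit$loglik + 2 * length(fit$coefficients)
  expect_equal(qaic(fit), aic_plain +
                 2 * length(fit$coefficients) * (fit$dispersion - 1))

  # appending pure-noise columns increases mean qAIC across refits
  diffs <- replicate(60, {
    y2 <- rpois(n, exp(2 + 0.2 * X[, "x"]))
    f1 <- fit_quasipoisson(list(X = X, y = y2, mask = rep(TRUE, n),
                                cb_cols = integer(0)))
    Xn <- cbind(X, noise = rnorm(n))
    f2 <- fit_quasipoisson(list(X = Xn, y = y2, mask = rep(TRUE, n),
                                cb_cols = integer(0)))
    qaic(f2) - qaic(f1)
  })
  expect_gt(mean(diffs), 0)
})

test_that("spec selection returns single candidates unchanged and scores by qAIC", {
  ser <- make_test_series(seed = 8, years = 3, overdispersion = 1)
  single <- knot_candidate(c(10, 75, 90), 2L)
  sel <- select_spec(ser, list(single))
  expect_identical(sel$var_percentiles, single$var_percentiles)
  expect_identical(sel$n_lag_knots, single$n_lag_knots)
  expect_true(is.finite(sel$qaic))

  cands <- list(knot_candidate(c(10, 75, 90), 2L), knot_candidate(50, 1L))
  sel2 <- select_spec(ser, cands)
  scores <- vapply(cands, function(cand) {
    spec <- default_crossbasis_spec(ser$tmean, cand$var_percentiles,
                                    cand$n_lag_knots)
    qaic(fit_quasipoisson(build_design(ser, build_crossbasis(ser$tmean, spec))))
  }, numeric(1))
  expect_equal(sel2$qaic, min(scores))
})
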