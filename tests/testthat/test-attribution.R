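test_that("daily attributable deaths follow the closed form", {
  curve <- make_linear_curve(slope = log(1.2) / 10, mmt = 16)
  # RR = 1 at the MMT -> AN = 0
  da0 <- daily_attributable(100, 16, curve)
  expect_equal(da0$an, 0)
  expect_identical(da0$component, "none")
  # RR = 1.2 -> AN = 100 * (1 - 1/1.2)
  da <- daily_attributable(100, 26, curve)
  expect_equal(da$an, 100 * (1 - 1 / 1.2), tolerance = 1e-12)
  expect_identical(da$component, "heat")
  # labelling by temperature side only
  expect_identical(daily_attributable(100, 13, curve)$component, "cold")
  expect_error(daily_attributable(-5, 20, curve), "negative")
})

test_that("decade aggregation sums AN and computes AF over the same days", {
  dates <- seq(as.Date("2010-01-01"), as.Date("2029-12-31"), by = 1)
  n <- length(dates)
  yr <- as.integer(format(dates, "%Y"))
  deaths <- rep(1000 / 3653, n)  # about 1000 deaths per decade
  deaths[yr < 2020] <- 1000 / sum(yr < 2020)
  deaths[yr >= 2020] <- 1000 / sum(yr >= 2020)
  an <- ifelse(yr < 2020, 10 / sum(yr < 2020), 30 / sum(yr >= 2020))
  daily <- data.frame(an = an, component = "heat")
  res <- aggregate_decades(dates, deaths, daily,
                           list(c(2010, 2019), c(2020, 2029)))
  heat <- res[res$component == "heat", ]
  expect_equal(heat$an, c(10, 30), tolerance = 1e-9)
  expect_equal(heat$af, c(1.0, 3.0), tolerance = 1e-9)
  # heat + cold = total per decade
  tot <- res[res$component == "total", ]
  cold <- res[res$component == "cold", ]
  expect_equal(heat$an + cold$an, tot$an)
  # all-zero AN propagates to zero AF
  res0 <- aggregate_decades(dates, deaths,
                            data.frame(an = rep(0, n), component = "heat"),
                            list(c(2010, 2019), c(2020, 2029)))
  expect_true(all(res0$an == 0) && all(res0$af == 0))
  expect_error(
    aggregate_decades(dates, rep(0, n), daily, list(c(2010, 2019))),
    "zero total deaths")
})

test_that("change ratios reproduce published worked examples", {
  expect_equal(change_ratio(540, 107), 5.0)
  expect_equal(change_ratio(1577, 136), 11.6)
  expect_equal(change_ratio(100, 100), 1.0)
  expect_true(is.na(change_ratio(50, 0)))
  expect_true(is.na(change_ratio(50, -10)))
  # half-away-from-zero, computed from unrounded inputs
  expect_equal(round_half_away(c(2.25, -2.25, 11.595), 1), c(2.3, -2.3, 11.6))
})

test_that("vectorised attribution matches the day-loop oracle", {
  ser <- make_test_series(seed = 16, years = 3)
  fr <- fit_region(ser, 16, "fixed_knots")
  idx <- 22:1021
  da <- daily_attributable(ser$deaths[idx], ser$tmean[idx], fr$curve,
                           adaptation = 0.2)
  oracle <- attribution_loop_oracle(ser$deaths[idx], ser$tmean[idx],
                                    fr$curve, adaptation = 0.2)
  expect_lt(max(abs(da$an - oracle$an)), 1e-9)
  expect_identical(da$component, oracle$component)
})

test_that("Monte-Carlo intervals behave: degenerate vcov, containment, sign", {
  ser <- gen_region_series("r", true_surface(), start = "2000-01-01",
                           end = "2009-12-31", censor_threshold = 0,
                           seed = 17)
  fr <- fit_region(ser, 16, "fixed_knots")
  dec <- list(c(2000, 2009))

  # zero covariance collapses the interval onto the point estimate
  curve0 <- fr$curve
  curve0$vcov <- matrix(0, 4, 4)
  res0 <- montecarlo_ci(curve0, ser$deaths, ser$tmean, ser$date, dec,
                        n_draws = 100, seed = 3)
  expect_equal(res0$lo95, res0$an, tolerance = 1e-9)
  expect_equal(res0$hi95, res0$an, tolerance = 1e-9)

  # with the fitted covariance, the point estimate lies inside the CI and
  # heat + cold = total
  res <- montecarlo_ci(fr$curve, ser$deaths, ser$tmean, ser$date, dec,
                       n_draws = 400, seed = 3)
  expect_true(all(res$lo95 <= res$an & res$an <= res$hi95))
  h <- res$an[res$component == "heat"]
  co <- res$an[res$component == "cold"]
  expect_equal(h + co, res$an[res$component == "total"])
  # reproducible given the seed
  res2 <- montecarlo_ci(fr$curve, ser$deaths, ser$tmean, ser$date, dec,
                        n_draws = 400, seed = 3)
  expect_identical(res, res2)

  # a curve dipping below RR = 1 on the heat side yields negative heat AN
  dipping <- make_linear_curve(slope = -0.01, mmt = 16)
  da <- daily_attributable(rep(50, 30), seq(17, 24, length.out = 30), dipping)
  expect_true(all(da$an < 0))
})
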