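test_that("baseline death climatology averages by calendar day", {
  dates <- seq(as.Date("2000-01-01"), as.Date("2001-12-31"), by = 1)
  ser <- daily_series("r", dates, rep(10, length(dates)),
                      rep(5, length(dates)))
  clim <- baseline_death_series(ser)
  expect_length(clim, 366L)
  expect_true(all(clim == 10))

  deaths <- ifelse(format(dates, "%Y") == "2000", 8, 12)
  ser2 <- daily_series("r", dates, deaths, rep(5, length(dates)))
  clim2 <- baseline_death_series(ser2)
  expect_equal(unname(clim2["01-01"]), 10)
  # Feb 29 imputed as the Feb 28 / Mar 1 average
  expect_equal(unname(clim2["02-29"]),
               mean(c(clim2["02-28"], clim2["03-01"])))
  # implied deaths over a non-leap future year = sum of the 365 entries
  yr2101 <- seq(as.Date("2101-01-01"), as.Date("2101-12-31"), by = 1)
  keys <- format(yr2101, "%m-%d")
  expect_equal(sum(clim2[keys]), sum(clim2[names(clim2) != "02-29"]))
})

test_that("population factors interpolate linearly from five-year anchors", {
  traj <- gen_population(5.4e6, 6.8e6, c(2010, 2100))
  expect_equal(population_factor(traj, 2010), 1)
  expect_equal(round(population_factor(traj, 2100), 3), 1.259)
  # midpoint anchor is the arithmetic mean of the endpoints
  expect_equal(traj$population[traj$anchor_years == 2055],
               mean(c(5.4e6, 6.8e6)))
  expect_error(population_factor(traj, 2105), "anchor range")

  small <- population_trajectory(c(2010, 2015), c(100, 110))
  expect_equal(population_factor(small, 2012), 1.04)
  small$enabled <- FALSE
  expect_equal(population_factor(small, 2012), 1)

  flat <- gen_population(2e6, 2e6, c(2010, 2100))
  expect_true(all(population_factor(flat, seq(2010, 2100, 7)) == 1))
})

test_that("an ensemble of identical members reproduces one member", {
  ser <- gen_region_series("r", true_surface(), start = "2000-01-01",
                           end = "2005-12-31", censor_threshold = 0, seed = 19)
  fr <- fit_region(ser, 16, "fixed_knots")
  clim <- baseline_death_series(ser)
  traj <- gen_population(enabled = FALSE)
  member <- gen_climate(climate_gen_spec(warming_by_2100 = 3, seed = 5),
                        "2010-01-01", "2039-12-31")
  mk <- function(id) list(model_id = id, dates = member$date,
                          tmean = member$tmean)
  dec <- list(c(2010, 2019), c(2020, 2029), c(2030, 2039))
  one <- project_scenario(fr$curve, climate_ensemble("s", list(mk("a"))),
                          clim, traj, decades = dec, n_draws = 150, seed = 4)
  three <- project_scenario(fr$curve,
                            climate_ensemble("s", list(mk("a"), mk("b"),
                                                       mk("c"))),
                            clim, traj, decades = dec, n_draws = 150, seed = 4)
  expect_equal(one$an, three$an, tolerance = 1e-12)
  expect_equal(one$af, three$af, tolerance = 1e-12)
  # pooled draws are three copies of the member's draws, so the empirical
  # quantiles agree up to interpolation at the larger sample size
  width <- pmax(one$hi95 - one$lo95, 1)
  expect_true(all(abs(one$lo95 - three$lo95) < 0.05 * width))
  expect_true(all(abs(one$hi95 - three$hi95) < 0.05 * width))
})

test_that("attributable numbers are exactly linear in the population factor", {
  ser <- gen_region_series("r", true_surface(), start = "2000-01-01",
                           end = "2005-12-31", censor_threshold = 0, seed = 23)
  fr <- fit_region(ser, 16, "fixed_knots")
  clim <- baseline_death_series(ser)
  ens <- gen_projection_members(climate_gen_spec(seed = 31), "s",
                                warming_range = c(2, 4), n_members = 2,
                                start = "2010-01-01", end = "2029-12-31")
  dec <- list(c(2010, 2019), c(2020, 2029))
  flat <- population_trajectory(c(2010, 2030), c(1, 1))
  ref <- project_scenario(fr$curve, ens, clim, flat, decades = dec,
                          n_draws = 120, seed = 9)
  # a constant population factor of 2 scales baseline deaths by 2 everywhere
  dbl <- project_scenario(fr$curve, ens, clim * 2, flat, decades = dec,
                          n_draws = 120, seed = 9)
  expect_equal(dbl$an, 2 * ref$an, tolerance = 1e-9)
  expect_equal(dbl$af, ref$af, tolerance = 1e-9)  # AF invariant to scale
})

test_that("uniform warming does not decrease heat AN on a rising heat curve", {
  curve <- make_linear_curve(slope = 0.03, mmt = 16)
  clim_dates <- seq(as.Date("2010-01-01"), as.Date("2019-12-31"), by = 1)
  base <- climate_gen_spec(seed = 77)
  cl <- gen_climate(base, "2010-01-01", "2019-12-31")
  deaths <- rep(10, length(clim_dates))
  dec <- list(c(2010, 2019))
  an_at <- function(delta) {
    da <- daily_attributable(deaths, cl$tmean + delta, curve)
    res <- aggregate_decades(cl$date, deaths, da, dec)
    res$an[res$component == "heat"]
  }
  vals <- vapply(c(0, 0.5, 1, 2, 4), an_at, numeric(1))
  expect_true(all(diff(vals) >= 0))
})
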