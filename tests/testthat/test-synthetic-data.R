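test_that("true log relative risk surface follows its closed form", {
  cfg <- synth_config(mmt_true = 19, slope_true = 0.05, cold_slope_true = 0,
                      lag_decay = 0.5)
  expect_equal(true_log_rr(19, 0, cfg), 0)
  expect_equal(true_log_rr(21, 0, cfg), 0.10)
  expect_equal(true_log_rr(21, 3, cfg), 0.10 * 0.5^3)
  # cold arm
  cfg2 <- synth_config(slope_true = 0.04, cold_slope_true = 0.02, lag_decay = 0.5)
  expect_equal(true_log_rr(17, 0, cfg2), 0.04)
  expect_equal(true_log_rr(17, 2, cfg2), 0.04 * 0.25)
  expect_error(true_log_rr(21, 11, cfg), class = "heatmort_value_error")
  expect_error(true_log_rr(21, -1, cfg), class = "heatmort_value_error")
})

test_that("synth_config rejects invalid parameters", {
  expect_error(synth_config(lag_decay = 1), class = "heatmort_config_error")
  expect_error(synth_config(baseline_rate = 0), class = "heatmort_config_error")
  expect_error(synth_config(slope_true = -0.1), class = "heatmort_config_error")
  expect_error(synth_config(year_start = 2000, year_end = 1999),
               class = "heatmort_config_error")
  expect_error(synth_config(n_units = 3, unit_temp_offsets = c(0, 1)),
               class = "heatmort_config_error")
})

test_that("identical configurations generate identical panels", {
  cfg <- synth_config(n_units = 3, year_start = 2000, year_end = 2001, seed = 9)
  p1 <- generate_panel(cfg)
  p2 <- generate_panel(cfg)
  expect_identical(p1$tmean, p2$tmean)
  expect_identical(p1$deaths, p2$deaths)
})

test_that("null surface reproduces the baseline rate", {
  # >= 1e5 unit-days; every systematic effect off, only mean-one stratum noise
  cfg <- synth_config(n_units = 25, year_start = 1990, year_end = 2000,
                      slope_true = 0, cold_slope_true = 0,
                      baseline_seasonality = 0, baseline_trend_per_decade = 0,
                      warming_per_decade = 0, baseline_rate = 0.3, seed = 5)
  p <- generate_panel(cfg)
  expect_gte(nrow(p), 1e5)
  expect_true(all(p$deaths >= 0))
  expect_true(all(p$deaths == round(p$deaths)))
  # lognormal(mean-one) mixing adds mu^2*(exp(sd^2)-1) to the Poisson variance
  v <- 0.3 + 0.3^2 * (exp(0.2^2) - 1)
  mcse <- sqrt(v / nrow(p))
  expect_lt(abs(mean(p$deaths) - 0.3), 3 * mcse)
})

test_that("temperature noise has the configured AR(1) autocorrelation", {
  cfg <- synth_config(n_units = 1, year_start = 1970, year_end = 1997,
                      temp_amplitude = 0, warming_per_decade = 0,
                      ar1_rho = 0.75, seed = 11)
  p <- generate_panel(cfg)
  expect_gte(nrow(p), 1e4)
  x <- p$tmean - mean(p$tmean)
  rho_hat <- stats::cor(x[-1], x[-length(x)])
  expect_lt(abs(rho_hat - 0.75), 0.05)
})

test_that("cause thinning reduces counts proportionally", {
  base <- synth_config(n_units = 10, year_start = 2000, year_end = 2004,
                       slope_true = 0, cold_slope_true = 0,
                       baseline_seasonality = 0, baseline_trend_per_decade = 0,
                       seed = 3)
  thin <- synth_config(n_units = 10, year_start = 2000, year_end = 2004,
                       slope_true = 0, cold_slope_true = 0,
                       baseline_seasonality = 0, baseline_trend_per_decade = 0,
                       cause_thinning = 0.2, seed = 3)
  m0 <- mean(generate_panel(base)$deaths)
  m1 <- mean(generate_panel(thin)$deaths)
  expect_lt(abs(m1 / m0 - 0.8), 0.05)
})

test_that("scenario generator reproduces configured bias and warming", {
  ref <- generate_panel(synth_config(n_units = 2, year_start = 1980,
                                     year_end = 2014, warming_per_decade = 0,
                                     seed = 21))
  ry <- 1980:2014  # >= 30 overlap years

  # unbiased member: historical monthly means match the reference within noise
  s0 <- generate_scenario(scenario_config("m", "hist", bias_mean = 0,
                                          bias_scale = 1, warming_per_decade = 0,
                                          year_start = 1980, year_end = 2014,
                                          seed = 4), ref)
  mon_ref <- tapply(ref$tmean, format(ref$date, "%m"), mean)
  mon_s0 <- tapply(s0$tmean, format(s0$date, "%m"), mean)
  expect_lt(max(abs(mon_s0 - mon_ref)), 0.5)

  # +2 degree member
  s2 <- generate_scenario(scenario_config("m", "hist", bias_mean = 2,
                                          bias_scale = 1, warming_per_decade = 0,
                                          year_start = 1980, year_end = 2014,
                                          seed = 4), ref)
  mon_s2 <- tapply(s2$tmean, format(s2$date, "%m"), mean)
  expect_lt(max(abs(mon_s2 - mon_ref - 2)), 0.5)
  expect_lt(abs(mean(s2$tmean) - mean(s0$tmean) - 2), 1e-10)

  # two pathways from one seed differ only by the warming term
  p85 <- generate_scenario(scenario_config("m", "rcp85", warming_per_decade = 0.45,
                                           year_start = 2000, year_end = 2030,
                                           seed = 7), ref)
  p45 <- generate_scenario(scenario_config("m", "rcp45", warming_per_decade = 0.18,
                                           year_start = 2000, year_end = 2030,
                                           seed = 7), ref)
  yrs <- as.numeric(format(p85$date, "%Y"))
  expect_equal(p85$tmean - p45$tmean, (0.45 - 0.18) * (yrs - 2000) / 10,
               tolerance = 1e-12)

  # scenario must overlap the reference years
  expect_error(generate_scenario(scenario_config("m", "x", year_start = 2050,
                                                 year_end = 2100), ref),
               class = "heatmort_config_error")
})
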