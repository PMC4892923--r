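# Synthetic-city generator: determinism, degenerate limits, and the
# closed-form seasonal cycle.

test_that("degenerate parameters give a constant series at the seasonal mean", {
  cfg <- sim_config(years = 2, seasonal_amplitude = 0, diurnal_amplitude = 0,
                    anomaly_sd = 0, intraday_sd = 0, obs_noise_sd = 0,
                    heatwave_rate = 0, heatwave_bump = 0, seasonal_mean = 17.5)
  s <- simulate_temperature(cfg)
  expect_equal(unique(s$temp), 17.5)
  expect_equal(nrow(s), (365 + 365) * 24)
  expect_true(all(diff(as.numeric(s$time)) == 3600))
})

test_that("same config and seed reproduce identical output", {
  cfg <- sim_config(years = 2, seed = 99)
  a <- simulate_temperature(cfg)
  b <- simulate_temperature(cfg)
  expect_identical(a, b)
  ma <- simulate_city(cfg)
  mb <- simulate_city(cfg)
  expect_identical(ma$deaths, mb$deaths)
  expect_identical(ma$truth, mb$truth)
  # different seed changes the draw
  expect_false(identical(a$temp,
                         simulate_temperature(sim_config(years = 2, seed = 100))$temp))
})

test_that("July-January contrast matches numerical integration of the seasonal sinusoid", {
  cfg <- sim_config(years = 10, seasonal_amplitude = 10, diurnal_amplitude = 0,
                    anomaly_sd = 2, intraday_sd = 0, obs_noise_sd = 0.3,
                    heatwave_rate = 0, seed = 3)
  s <- simulate_temperature(cfg)
  mo <- as.integer(format(s$time, "%m"))
  observed <- mean(s$temp[mo == 7]) - mean(s$temp[mo == 1])
  # oracle: direct numerical integration of the configured sinusoid over the
  # two months' day-of-year ranges
  sinusoid <- function(d) 10 * cos(2 * pi * (d - 201) / 365.25)
  july <- integrate(sinusoid, 182, 213)$value / 31
  january <- integrate(sinusoid, 1, 32)$value / 31
  expected <- july - january
  # Monte-Carlo error: AR(1) day anomalies, sd 2, ~310 days per month-decade
  expect_lt(abs(observed - expected), 0.5)
})

test_that("missing injection flags the requested count as isolated gaps", {
  cfg <- sim_config(years = 2, seed = 5)
  s <- simulate_temperature(cfg)
  expect_identical(inject_missing(s, 0), s)

  m <- inject_missing(s, 0.034, seed = 11)
  expect_equal(sum(m$missing), round(0.034 * nrow(s)))
  expect_true(all(is.na(m$temp[m$missing])))

  # isolated mode: no two consecutive missing timestamps (direct scan)
  idx <- which(m$missing)
  expect_true(all(diff(idx) > 1))

  # determinism and error cases
  expect_identical(inject_missing(s, 0.01, seed = 2),
                   inject_missing(s, 0.01, seed = 2))
  expect_error(inject_missing(s, 0.6), class = "heatclock_config_error")
  expect_error(inject_missing(s, -0.1), class = "heatclock_config_error")
})

test_that("null-model mortality has the configured mean and dispersion", {
  cfg <- sim_config(years = 10, effect_slope = 0, trend_amplitude = 0,
                    baseline_rate = 10, overdispersion = 1, seed = 21)
  days <- seq(as.Date("2001-01-01"), by = "day", length.out = 3650)
  exposure <- data.frame(date = days, value = rep(20, 3650))
  out <- simulate_mortality(exposure, cfg)
  expect_equal(mean(out$deaths$deaths), 10,
               tolerance = 3 * sqrt(10 / 3650) / 10)
  expect_identical(out$truth$true_rr, 1.0)

  # overdispersed arm: empirical variance/mean ratio near the configured phi
  cfg2 <- sim_config(years = 10, effect_slope = 0, trend_amplitude = 0,
                     baseline_rate = 30, overdispersion = 1.5, seed = 22)
  out2 <- simulate_mortality(exposure, cfg2)
  ratio <- var(out2$deaths$deaths) / mean(out2$deaths$deaths)
  expect_gt(ratio, 1.5 * 0.8)
  expect_lt(ratio, 1.5 * 1.2)
})

test_that("the truth contrast is the hinge evaluated at realized quantiles", {
  cfg <- sim_config(years = 2, effect_slope = 0.02, seed = 13)
  days <- seq(as.Date("2001-01-01"), by = "day", length.out = 730)
  vals <- as.numeric(scale(sin(seq_len(730) / 20))) * 8 + 15
  exposure <- data.frame(date = days, value = vals)
  out <- simulate_mortality(exposure, cfg)
  q85 <- unname(quantile(vals, 0.85, type = 7))
  q99 <- unname(quantile(vals, 0.99, type = 7))
  thr <- unname(quantile(vals, cfg$effect_threshold_quantile, type = 7))
  # hand evaluation of the piecewise-linear effect
  expect_equal(out$truth$true_contrast,
               0.02 * max(0, q99 - thr) - 0.02 * max(0, q85 - thr))
  expect_equal(true_rr(out$truth), exp(out$truth$true_contrast))

  # doubling the slope squares the RR for identical exposure draws
  cfg2 <- sim_config(years = 2, effect_slope = 0.04, seed = 13)
  out2 <- simulate_mortality(exposure, cfg2)
  expect_equal(out2$truth$true_rr, out$truth$true_rr^2)
})

test_that("true_rr equals 1 exactly iff the effect slope is zero", {
  days <- seq(as.Date("2001-01-01"), by = "day", length.out = 730)
  exposure <- data.frame(date = days, value = rnorm(730, 15, 5))
  null <- simulate_mortality(exposure, sim_config(years = 2, effect_slope = 0))
  expect_identical(null$truth$true_rr, 1.0)
  eff <- simulate_mortality(exposure, sim_config(years = 2, effect_slope = 0.01))
  expect_gt(eff$truth$true_rr, 1)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(years = 1), class = "heatclock_config_error")
  expect_error(sim_config(cadence_minutes = 45), class = "heatclock_config_error")
  expect_error(sim_config(ar1_coefficient = 1), class = "heatclock_config_error")
  expect_error(sim_config(overdispersion = 0.5), class = "heatclock_config_error")
  expect_error(sim_config(baseline_rate = 0), class = "heatclock_config_error")
  expect_error(sim_config(effect_hour = 24), class = "heatclock_config_error")
  expect_error(sim_config(effect_hour = "median"), class = "heatclock_config_error")
  expect_error(sim_config(anomaly_sd = NA), class = "heatclock_config_error")
})
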