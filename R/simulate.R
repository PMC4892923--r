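#' Configuration for the synthetic-city generator
#'
#' Bundles every tunable of the synthetic city: the temperature process
#' (seasonal and diurnal sinusoids, AR(1) day-to-day anomalies, summer heat
#' waves, observation noise), the mortality process (baseline rate, winter
#' mortality excess, overdispersion), and the injected temperature effect
#' (which exposure variable carries it, at which lag, above which quantile,
#' with what log-linear slope).
#'
#' @param years number of simulated calendar years (>= 2).
#' @param cadence_minutes observation spacing in minutes; must divide 60 or
#'   equal 60.
#' @param seasonal_mean annual-mean temperature, degrees C.
#' @param seasonal_amplitude half-range of the annual sinusoid, degrees C
#'   (peak around 20 July).
#' @param diurnal_amplitude half-range of the within-day sinusoid, degrees C.
#' @param diurnal_peak_hour local-standard-time hour of the diurnal peak
#'   (default 16, placing the minimum in the early morning).
#' @param ar1_coefficient day-to-day anomaly autocorrelation in `[0, 1)`.
#' @param anomaly_sd stationary standard deviation of the daily anomaly,
#'   degrees C.
#' @param intraday_sd stationary sd of the hour-scale anomaly (an AR(1)
#'   process at observation resolution with correlation time
#'   `intraday_tau_hours`), degrees C.  This is the within-day weather —
#'   frontal passages, cloud cover — that makes different hours of the same
#'   day carry distinct information; without it all 24 hourly exposure
#'   variables would be deterministically linked.
#' @param intraday_tau_hours e-folding correlation time of the hour-scale
#'   anomaly, hours.
#' @param obs_noise_sd sd of independent per-observation noise, degrees C.
#' @param heatwave_rate expected heat-wave episodes per summer (May-Sep).
#' @param heatwave_bump added degrees C on heat-wave days.
#' @param baseline_rate expected deaths/day before modulation.
#' @param trend_amplitude relative seasonal mortality modulation (winter
#'   excess), on the log scale.
#' @param overdispersion variance inflation factor of daily counts (>= 1;
#'   1 = Poisson).
#' @param effect_hour hour 0-23 or a summary-metric name ("max", "min",
#'   "max_hr", "min_hr", "mean", "mean_hr", "mean24") carrying the true
#'   temperature effect.
#' @param effect_lag lag in days (0-3) at which the effect acts.
#' @param effect_threshold_quantile quantile of the effect variable above
#'   which the log mortality rate ramps linearly.
#' @param effect_slope log-rate increase per degree C above the threshold.
#' @param start_year first simulated calendar year.
#' @param seed master integer seed; per-component child seeds are derived
#'   from it by fixed offsets.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(years = 10,
                       cadence_minutes = 60,
                       seasonal_mean = 12,
                       seasonal_amplitude = 8,
                       diurnal_amplitude = 4,
                       diurnal_peak_hour = 16,
                       ar1_coefficient = 0.7,
                       anomaly_sd = 3.5,
                       intraday_sd = 2.5,
                       intraday_tau_hours = 6,
                       obs_noise_sd = 0.3,
                       heatwave_rate = 3,
                       heatwave_bump = 5,
                       baseline_rate = 40,
                       trend_amplitude = 0.1,
                       overdispersion = 1.3,
                       effect_hour = 15,
                       effect_lag = 0,
                       effect_threshold_quantile = 0.85,
                       effect_slope = 0.0064,
                       start_year = 2001,
                       seed = 1) {
  cfg <- list(years = years, cadence_minutes = cadence_minutes,
              seasonal_mean = seasonal_mean,
              seasonal_amplitude = seasonal_amplitude,
              diurnal_amplitude = diurnal_amplitude,
              diurnal_peak_hour = diurnal_peak_hour,
              ar1_coefficient = ar1_coefficient, anomaly_sd = anomaly_sd,
              intraday_sd = intraday_sd,
              intraday_tau_hours = intraday_tau_hours,
              obs_noise_sd = obs_noise_sd, heatwave_rate = heatwave_rate,
              heatwave_bump = heatwave_bump, baseline_rate = baseline_rate,
              trend_amplitude = trend_amplitude,
              overdispersion = overdispersion, effect_hour = effect_hour,
              effect_lag = effect_lag,
              effect_threshold_quantile = effect_threshold_quantile,
              effect_slope = effect_slope, start_year = start_year,
              seed = seed)
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  num <- c("seasonal_mean", "seasonal_amplitude", "diurnal_amplitude",
           "diurnal_peak_hour", "ar1_coefficient", "anomaly_sd",
           "intraday_sd", "intraday_tau_hours", "obs_noise_sd", "heatwave_rate", "heatwave_bump", "baseline_rate",
           "trend_amplitude", "overdispersion", "effect_lag",
           "effect_threshold_quantile", "effect_slope", "seed")
  for (f in num) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop_heatclock(sprintf("config field '%s' must be a finite number", f),
                     "heatclock_config_error")
    }
  }
  if (!is_count(cfg$years) || cfg$years < 2) {
    stop_heatclock("years must be an integer >= 2", "heatclock_config_error")
  }
  cm <- cfg$cadence_minutes
  if (!is_count(cm) || cm < 1 || 60 %% cm != 0) {
    stop_heatclock("cadence_minutes must divide 60 (e.g. 15, 20, 30, 60)",
                   "heatclock_config_error")
  }
  if (cfg$ar1_coefficient < 0 || cfg$ar1_coefficient >= 1) {
    stop_heatclock("ar1_coefficient must lie in [0, 1)", "heatclock_config_error")
  }
  if (cfg$overdispersion < 1) {
    stop_heatclock("overdispersion must be >= 1", "heatclock_config_error")
  }
  if (cfg$baseline_rate <= 0) {
    stop_heatclock("baseline_rate must be > 0", "heatclock_config_error")
  }
  if (!cfg$effect_lag %in% 0:3) {
    stop_heatclock("effect_lag must be 0, 1, 2 or 3", "heatclock_config_error")
  }
  eh <- cfg$effect_hour
  ok_hour <- (is.numeric(eh) && is_count(eh) && eh >= 0 && eh <= 23) ||
    (is.character(eh) && eh %in% summary_metric_names())
  if (!ok_hour) {
    stop_heatclock("effect_hour must be an hour 0-23 or a summary-metric name",
                   "heatclock_config_error")
  }
  invisible(cfg)
}

summary_metric_names <- function() {
  c("max", "max_hr", "min", "min_hr", "mean", "mean_hr", "mean24")
}

# canonical variable id of the effect-carrying exposure, e.g. "t15" or "max"
effect_variable_id <- function(cfg) {
  if (is.character(cfg$effect_hour)) cfg$effect_hour
  else sprintf("t%02d", as.integer(cfg$effect_hour))
}

#' Simulate a multi-year sub-hourly temperature series
#'
#' Temperature at each timestamp is the sum of an annual sinusoid (peak near
#' 20 July), a diurnal sinusoid (peak at `diurnal_peak_hour`), an AR(1)
#' day-level anomaly, an hour-scale AR(1) anomaly (within-day weather with
#' correlation time `intraday_tau_hours`), heat-wave bumps (Poisson-count
#' episodes of geometric mean-3-day duration confined to May-September),
#' and independent observation noise.  Timestamps are complete and strictly
#' increasing at the configured cadence over every calendar day of every
#' simulated year.  Output is deterministic given the config (including its
#' seed).
#'
#' @param config a [sim_config()].
#' @return An [obs_series()].
#' @export
simulate_temperature <- function(config) {
  validate_sim_config(config)
  day0 <- as.Date(sprintf("%d-01-01", config$start_year))
  day_end <- as.Date(sprintf("%d-12-31", config$start_year + config$years - 1))
  days <- seq(day0, day_end, by = "day")
  n_days <- length(days)
  per_day <- as.integer((24 * 60) / config$cadence_minutes)
  t0 <- as.POSIXct(paste(day0, "00:00:00"), tz = "UTC")
  time <- t0 + seq(0, by = config$cadence_minutes * 60,
                   length.out = n_days * per_day)

  doy <- frac_doy(time)
  hour <- (as.numeric(time) %% 86400) / 3600
  seasonal <- config$seasonal_mean +
    config$seasonal_amplitude * cos(2 * pi * (doy - 201) / 365.25)
  diurnal <- config$diurnal_amplitude *
    cos(2 * pi * (hour - config$diurnal_peak_hour) / 24)

  with_seed(child_seed(config$seed, 1), {
    # AR(1) anomaly at day resolution; anomaly_sd is the stationary sd
    phi <- config$ar1_coefficient
    anom <- numeric(n_days)
    if (config$anomaly_sd > 0) {
      innov <- rnorm(n_days, 0, config$anomaly_sd * sqrt(1 - phi^2))
      innov[1] <- rnorm(1, 0, config$anomaly_sd)
      anom <- as.numeric(stats::filter(innov, phi, method = "recursive"))
    }

    # hour-scale AR(1) anomaly at observation resolution (within-day weather)
    intraday <- 0
    if (config$intraday_sd > 0) {
      rho <- exp(-(config$cadence_minutes / 60) / config$intraday_tau_hours)
      innov <- rnorm(length(time), 0, config$intraday_sd * sqrt(1 - rho^2))
      innov[1] <- rnorm(1, 0, config$intraday_sd)
      intraday <- as.numeric(stats::filter(innov, rho, method = "recursive"))
    }

    # heat-wave episodes: per summer, Poisson count, geometric duration
    bump <- numeric(n_days)
    if (config$heatwave_rate > 0 && config$heatwave_bump != 0) {
      day_doy <- frac_doy(as.POSIXct(paste(days, "00:00:00"), tz = "UTC"))
      yr <- as.integer(format(days, "%Y"))
      for (y in unique(yr)) {
        summer <- which(yr == y & day_doy >= 121 & day_doy <= 273)
        n_ep <- rpois(1, config$heatwave_rate)
        if (n_ep > 0 && length(summer) > 0) {
          starts <- sample(summer, n_ep, replace = TRUE)
          durs <- rgeom(n_ep, 1 / 3) + 1
          for (i in seq_len(n_ep)) {
            idx <- starts[i]:min(starts[i] + durs[i] - 1, n_days)
            bump[idx] <- bump[idx] + config$heatwave_bump
          }
        }
      }
    }

    noise <- if (config$obs_noise_sd > 0) {
      rnorm(length(time), 0, config$obs_noise_sd)
    } else {
      0
    }
    day_idx <- rep(seq_len(n_days), each = per_day)
    temp <- seasonal + diurnal + anom[day_idx] + intraday + bump[day_idx] + noise
    obs_series(time, temp)
  })
}

#' Flag a fraction of observations as missing
#'
#' Marks `round(fraction * n)` records missing.  In the default
#' `"isolated"` mode no two consecutive records are flagged (matching
#' station archives in which the large majority of gaps are isolated single
#' missing values); `"random"` mode flags records uniformly at random.
#'
#' @param series an [obs_series()].
#' @param fraction proportion of records to flag, in `[0, 0.5)`.
#' @param seed integer seed.
#' @param mode `"isolated"` (default) or `"random"`.
#' @return The series with flagged records set missing (`temp = NA`).
#' @export
inject_missing <- function(series, fraction, seed = 1,
                           mode = c("isolated", "random")) {
  mode <- match.arg(mode)
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      !is.finite(fraction) || fraction < 0 || fraction >= 0.5) {
    stop_heatclock("fraction must lie in [0, 0.5)", "heatclock_config_error")
  }
  n <- nrow(series)
  m <- round(fraction * n)
  if (m == 0) {
    return(series)
  }
  idx <- with_seed(seed, {
    if (mode == "random") {
      sample.int(n, m)
    } else {
      taken <- logical(n)
      blocked <- logical(n)
      order_ <- sample.int(n)
      got <- 0L
      for (i in order_) {
        if (got == m) break
        if (!blocked[i]) {
          taken[i] <- TRUE
          blocked[i] <- TRUE
          if (i > 1) blocked[i - 1] <- TRUE
          if (i < n) blocked[i + 1] <- TRUE
          got <- got + 1L
        }
      }
      # greedy placement can fall short near the density limit; top up with
      # uniformly chosen (possibly adjacent) records
      if (got < m) {
        pool <- which(!taken)
        taken[sample(pool, m - got)] <- TRUE
      }
      which(taken)
    }
  })
  series$missing[idx] <- TRUE
  series$temp[idx] <- NA_real_
  series
}

#' Simulate daily death counts with a known temperature effect
#'
#' Draws daily all-cause death counts from an overdispersed count
#' distribution (gamma-Poisson mixture with `Var = overdispersion * mean`;
#' plain Poisson when `overdispersion = 1`) with log rate
#' `log(baseline_rate) + trend + f_true(exposure)`, where the trend is a
#' winter-peaking annual sinusoid of relative amplitude `trend_amplitude`
#' and `f_true` is zero below the configured threshold quantile of the
#' exposure and linear with slope `effect_slope` above it (a hockey-stick
#' effect on the exposure's own scale).
#'
#' The returned truth record carries the ground-truth analogue of the
#' percentile-contrast relative risk: `true_contrast` is
#' `f_true(q99) - f_true(q85)` computed from the realized exposure
#' quantiles, and `true_rr = exp(true_contrast)`.
#'
#' @param exposure data frame with columns `date` and `value`: the daily
#'   series of the effect-carrying variable, already lag-shifted so that
#'   row `d` is the exposure relevant to deaths on date `d`.  Must cover
#'   every simulated day with finite values.
#' @param config a [sim_config()].
#' @return A list with `deaths` (data frame `date`, `deaths`) and `truth`
#'   (class `sim_truth`).
#' @export
simulate_mortality <- function(exposure, config) {
  validate_sim_config(config)
  if (!is.data.frame(exposure) || !all(c("date", "value") %in% names(exposure))) {
    stop_heatclock("exposure must be a data frame with columns date, value",
                   "heatclock_alignment_error")
  }
  if (anyNA(exposure$value) || !all(is.finite(exposure$value))) {
    stop_heatclock("exposure must be finite on every simulated day",
                   "heatclock_alignment_error")
  }
  dates <- as.Date(exposure$date)
  if (any(diff(as.integer(dates)) != 1L)) {
    stop_heatclock("exposure dates must be consecutive calendar days",
                   "heatclock_alignment_error")
  }
  x <- exposure$value
  thr <- unname(quantile(x, config$effect_threshold_quantile, type = 7))
  f_true <- function(v) config$effect_slope * pmax(0, v - thr)

  doy <- frac_doy(as.POSIXct(paste(dates, "00:00:00"), tz = "UTC"))
  log_mu <- log(config$baseline_rate) +
    config$trend_amplitude * cos(2 * pi * (doy - 15) / 365.25) +
    f_true(x)
  mu <- exp(log_mu)

  counts <- with_seed(child_seed(config$seed, 3), {
    if (config$overdispersion == 1) {
      rpois(length(mu), mu)
    } else {
      size <- mu / (config$overdispersion - 1)
      rnbinom(length(mu), mu = mu, size = size)
    }
  })

  q85 <- unname(quantile(x, 0.85, type = 7))
  q99 <- unname(quantile(x, 0.99, type = 7))
  contrast <- f_true(q99) - f_true(q85)
  truth <- structure(
    list(true_contrast = contrast,
         true_rr = exp(contrast),
         effect_cell = list(variable = effect_variable_id(config),
                            lag = as.integer(config$effect_lag)),
         threshold = thr, q85 = q85, q99 = q99,
         effect_slope = config$effect_slope),
    class = "sim_truth"
  )
  list(deaths = data.frame(date = dates, deaths = counts), truth = truth)
}

#' Ground-truth relative risk of a simulation
#'
#' @param truth a `sim_truth` record from [simulate_mortality()].
#' @return `exp(true_contrast)`, the ground-truth 99th-vs-85th percentile
#'   relative risk of the effect-carrying exposure.
#' @export
true_rr <- function(truth) {
  stopifnot(inherits(truth, "sim_truth"))
  exp(truth$true_contrast)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("<sim_truth> effect cell: %s lag %d\n",
              x$effect_cell$variable, x$effect_cell$lag))
  cat(sprintf("  true RR (q99 vs q85) = %.4f  (contrast %.5f on log scale)\n",
              x$true_rr, x$true_contrast))
  cat(sprintf("  threshold %.2f degC, q85 %.2f, q99 %.2f, slope %.4f/degC\n",
              x$threshold, x$q85, x$q99, x$effect_slope))
  invisible(x)
}

#' Simulate a complete synthetic city
#'
#' Convenience wrapper running the full generative chain: simulate the
#' temperature series, optionally flag missing observations, build the
#' daily metric table, extract and lag-shift the effect-carrying exposure
#' variable, and simulate mortality counts against it.  For death dates in
#' the first `effect_lag` days (whose lagged exposure precedes the record)
#' the same-day exposure is used, so that the mortality series covers every
#' simulated day.
#'
#' @param config a [sim_config()].
#' @param missing_fraction proportion of observations flagged missing
#'   before metric construction (isolated single gaps).
#' @return A list with elements `temps` ([obs_series()]), `metrics`
#'   (daily metric table), `deaths`, and `truth`.
#' @export
simulate_city <- function(config, missing_fraction = 0) {
  temps <- simulate_temperature(config)
  if (missing_fraction > 0) {
    temps <- inject_missing(temps, missing_fraction,
                            seed = child_seed(config$seed, 2))
  }
  metrics <- build_metric_table(temps)
  var_id <- effect_variable_id(config)
  lag <- as.integer(config$effect_lag)
  if (!all(metrics$complete)) {
    stop_heatclock("synthetic metric table has incomplete days; cannot define the true exposure",
                   "heatclock_alignment_error")
  }
  vals <- metrics[[var_id]]
  if (lag > 0) {
    vals <- c(vals[seq_len(lag)], vals[seq_len(length(vals) - lag)])
  }
  exposure <- data.frame(date = metrics$date, value = vals)
  mort <- simulate_mortality(exposure, config)
  list(temps = temps, metrics = metrics,
       deaths = mort$deaths, truth = mort$truth)
}
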