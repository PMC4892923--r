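# Shared fixtures, built in code.

# small synthetic city used across test files (2 years, hourly cadence)
small_city <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_city(sim_config(years = 2, seed = 7))
    cache
  }
})

# a converged fit of the small city's effect cell
small_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      city <- small_city()
      al <- lag_align(data.frame(date = city$metrics$date,
                                 value = city$metrics$t15),
                      lag = 0, deaths = city$deaths)
      cache <<- heatgam(al$deaths, al$exposure, al$time_index,
                        df_per_year = 5)
    }
    cache
  }
})

# hand-constructed heatgam object with a linear temperature term whose term
# effects and standard errors are exactly controlled; used to exercise the
# RR/CI arithmetic without fitting
fake_linear_fit <- function(beta_temp, var_temp, centre = 0) {
  structure(list(
    coefficients = c("(Intercept)" = 1, "temp.1" = beta_temp),
    cov_scaled = matrix(c(0, 0, 0, var_temp), 2, 2,
                        dimnames = list(c("(Intercept)", "temp.1"),
                                        c("(Intercept)", "temp.1"))),
    temp_spec = list(k = 2L, degree = 1L, interior = numeric(0),
                     boundary = c(-10, 10), linear = TRUE),
    temp_centering = centre,
    temp_range = c(-10, 10),
    n = 100L, edf = 2L, deviance = 1, phi = 1, gcv = 0.01,
    converged = TRUE
  ), class = "heatgam")
}

# percentile_set with chosen values, bypassing the data-driven constructor
fake_percentiles <- function(p_base, p99, baseline = 85) {
  structure(list(p_base = p_base, p90 = p_base, p99 = p99,
                 baseline = baseline, n = 1000L,
                 degenerate = p99 <= p_base),
            class = "percentile_set")
}

# observation series at an exact cadence with given temperatures
make_series <- function(start, temps, by_minutes = 60) {
  t0 <- as.POSIXct(start, tz = "UTC")
  obs_series(t0 + seq(0, by = by_minutes * 60, length.out = length(temps)),
             temps)
}
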