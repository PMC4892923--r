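# Exposure variables, year-round percentiles, and lag alignment.

#' Names of the 31 exposure variables
#'
#' The 24 hourly snapshot variables (`t00` .. `t23`) followed by the seven
#' daily summary metrics.
#'
#' @return Character vector of length 31.
#' @export
exposure_variables <- function() {
  c(sprintf("t%02d", 0:23), summary_metric_names())
}

#' Year-round percentiles of one exposure variable
#'
#' Empirical quantiles (linear interpolation of order statistics, the
#' standard type-7 convention) of a daily exposure series pooled over all
#' calendar days of all study years — percentiles are deliberately not
#' summer-only, so the 85th percentile corresponds to roughly the 55th
#' hottest day of an average year.
#'
#' @param values numeric daily series (at least 365 values).
#' @param baseline baseline percentile, 85 (default) or 90.
#' @return A list of class `percentile_set` with elements `p_base`, `p90`,
#'   `p99`, `baseline`, `n`, and `degenerate` (TRUE when `p99 == p_base`,
#'   in which case the relative-risk contrast is undefined and the cell is
#'   excluded).
#' @export
compute_percentiles <- function(values, baseline = 85) {
  values <- values[!is.na(values)]
  if (length(values) < 365) {
    stop_heatclock("need at least 365 daily values for an annual percentile basis",
                   "heatclock_percentile_error")
  }
  if (!baseline %in% c(85, 90)) {
    stop_heatclock("baseline percentile must be 85 or 90", "heatclock_percentile_error")
  }
  q <- unname(quantile(values, c(baseline / 100, 0.90, 0.99), type = 7))
  structure(
    list(p_base = q[1], p90 = q[2], p99 = q[3],
         baseline = baseline, n = length(values),
         degenerate = q[3] <= q[1]),
    class = "percentile_set"
  )
}

#' @export
print.percentile_set <- function(x, ...) {
  cat(sprintf("<percentile_set> p%d = %.3f, p99 = %.3f (n = %d)%s\n",
              x$baseline, x$p_base, x$p99, x$n,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Pair death counts with lagged exposure values
#'
#' A death on date d is paired with the exposure on date d - lag (lag 0 is
#' the day of death, lag 1 the day before, and so on).  Death dates whose
#' lagged exposure is unavailable — before the start of the exposure record
#' or on a day excluded from the metric table — are dropped and counted.
#'
#' @param exposure data frame with columns `date` and `value` (one exposure
#'   variable's daily series; `NA` values count as unavailable).
#' @param lag integer lag in days, 0-3.
#' @param deaths data frame with columns `date` and `deaths`.
#' @return A data frame with columns `date` (death date), `time_index`
#'   (integer day counter from the first death date), `deaths`, and
#'   `exposure`; attribute `n_dropped` counts dropped death dates.
#' @export
lag_align <- function(exposure, lag, deaths) {
  if (!lag %in% 0:3) {
    stop_heatclock("lag must be 0, 1, 2 or 3", "heatclock_alignment_error")
  }
  ddates <- as.Date(deaths$date)
  edates <- as.Date(exposure$date)
  want <- ddates - lag
  idx <- match(want, edates)
  val <- exposure$value[idx]
  keep <- !is.na(val)
  if (!any(keep)) {
    stop_heatclock("no death date has a lagged exposure value", "heatclock_alignment_error")
  }
  out <- data.frame(
    date = ddates[keep],
    time_index = as.integer(ddates[keep] - min(ddates)) + 1L,
    deaths = deaths$deaths[keep],
    exposure = val[keep]
  )
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Enumerate the full exposure-by-lag model grid
#'
#' Builds the 124 model cells — 31 exposure variables crossed with lags
#' 0-3 — in deterministic lag-major order (within each lag: hours `t00` ..
#' `t23`, then the seven summary metrics).  Each variable's percentile set
#' is computed once from its complete-day values pooled over all years.
#'
#' @param table a `daily_metrics` table from [build_metric_table()].
#' @param baseline baseline percentile (85 or 90) for the percentile sets.
#' @return A list of class `exposure_grid`; each element has `variable`,
#'   `lag`, and `percentiles` (a [compute_percentiles()] result).
#' @export
enumerate_exposures <- function(table, baseline = 85) {
  vars <- exposure_variables()
  keep <- table$complete
  psets <- lapply(vars, function(v) compute_percentiles(table[[v]][keep], baseline))
  names(psets) <- vars
  cells <- list()
  for (lag in 0:3) {
    for (v in vars) {
      cells[[length(cells) + 1L]] <- list(variable = v, lag = lag,
                                          percentiles = psets[[v]])
    }
  }
  class(cells) <- "exposure_grid"
  cells
}

#' @export
print.exposure_grid <- function(x, ...) {
  cat(sprintf("<exposure_grid> %d cells (%d variables x 4 lags)\n",
              length(x), length(x) / 4L))
  invisible(x)
}
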