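# Daily exposure metrics from sub-hourly observations.
#
# Day boundaries are midnight-to-midnight on a fixed local-standard-time
# clock (the series' POSIXct times are stored in a DST-free timezone), so a
# calendar day is simply [00:00, 24:00) of that clock.

# Vectorised top-of-hour snapshot selection.  For each (day, hour) target
# the observation minimising |timestamp - target| within a +/-30 min window
# is chosen; exact distance ties resolve to the earlier observation.
# Returns an n_days x 24 matrix (NA where no observation is in-window).
snapshot_matrix <- function(time, temp, days) {
  tnum <- as.numeric(time)
  n_days <- length(days)
  day0 <- as.numeric(as.POSIXct(paste(days, "00:00:00"), tz = "UTC"))
  targets <- rep(day0, each = 24L) + rep(3600 * (0:23), times = n_days)
  i <- findInterval(targets, tnum)
  n <- length(tnum)
  d_before <- ifelse(i >= 1, targets - tnum[pmax(i, 1L)], Inf)
  d_after <- ifelse(i < n, tnum[pmin(i + 1L, n)] - targets, Inf)
  use_before <- d_before <= d_after        # earlier wins ties
  pick <- ifelse(use_before, i, i + 1L)
  dist <- pmin(d_before, d_after)
  val <- ifelse(dist <= 1800, temp[pmax(pmin(pick, n), 1L)], NA_real_)
  matrix(val, nrow = n_days, ncol = 24L, byrow = TRUE)
}

#' Top-of-hour temperature snapshots for one day
#'
#' For each hour h of the requested calendar day, selects the observation
#' closest to h:00 within a symmetric 30-minute window; when an observation
#' before and one after the hour are equally distant the earlier one is
#' used.  Hours with no in-window observation are returned as `NA`.
#' Missing records are not eligible (interpolate first with
#' [interpolate_missing()]).
#'
#' @param series an [obs_series()].
#' @param day a `Date` (or something coercible).
#' @return Named numeric vector of 24 temperatures (`t00` .. `t23`).
#' @export
hourly_snapshot <- function(series, day) {
  day <- as.Date(day)
  ok <- !series$missing
  snaps <- snapshot_matrix(series$time[ok], series$temp[ok], day)[1L, ]
  names(snaps) <- sprintf("t%02d", 0:23)
  snaps
}

#' Daily summary metrics for one day
#'
#' Computes the seven daily summary metrics from one calendar day of
#' observations: `max`/`min` are the extremes over *all* observations of
#' the day (as a max/min thermometer would record, free to occur at any
#' time); `max_hr`/`min_hr` are the extremes over only the 24 top-of-hour
#' snapshots; `mean = (max + min)/2`; `mean_hr = (max_hr + min_hr)/2`;
#' `mean24` is the average of the 24 snapshots.
#'
#' @param series an [obs_series()] (interpolated, or with no missing values
#'   on the requested day).
#' @param day a `Date`.
#' @return A one-row data frame: `date`, `t00`..`t23`, the seven summary
#'   metrics, `interpolated_count`, and a `complete` flag (all 24 snapshots
#'   present).  Incomplete days are flagged and excluded from modelling.
#' @export
daily_summaries <- function(series, day) {
  day <- as.Date(day)
  tab <- build_metric_table(series, days = day)
  tab
}

#' Build the daily exposure metric table
#'
#' Applies missing-value interpolation, top-of-hour snapshot selection and
#' daily summary computation to every calendar day spanned by the series.
#' Days with any unrecoverable hour (no observation within 30 minutes of
#' the top of the hour) are flagged incomplete and excluded from modelling
#' rather than partially imputed.
#'
#' @param series an [obs_series()].
#' @param days optional vector of `Date`s to restrict to (default: every
#'   calendar day spanned by the series).
#' @return A data frame of class `daily_metrics` with one row per day:
#'   `date`, snapshot columns `t00`..`t23`, summary columns `max`, `min`,
#'   `max_hr`, `min_hr`, `mean`, `mean_hr`, `mean24`,
#'   `interpolated_count`, and `complete`.  Attributes `n_interpolated`
#'   and `n_excluded` report totals.
#' @export
build_metric_table <- function(series, days = NULL) {
  if (nrow(series) == 0) {
    stop_heatclock("empty observation series", "heatclock_ingest_error")
  }
  series <- interpolate_missing(series)
  obs_day <- as.Date(floor(as.numeric(series$time) / 86400), origin = "1970-01-01")
  if (is.null(days)) {
    days <- seq(min(obs_day), max(obs_day), by = "day")
  } else {
    days <- as.Date(days)
  }

  snaps <- snapshot_matrix(series$time, series$temp, days)

  di <- match(obs_day, days)
  keep <- !is.na(di)
  grp <- factor(di[keep], levels = seq_along(days))
  all_max <- suppressWarnings(as.numeric(tapply(series$temp[keep], grp, max)))
  all_min <- suppressWarnings(as.numeric(tapply(series$temp[keep], grp, min)))
  interp_n <- as.numeric(tapply(series$interpolated[keep], grp, sum))
  interp_n[is.na(interp_n)] <- 0
  all_max[!is.finite(all_max)] <- NA_real_
  all_min[!is.finite(all_min)] <- NA_real_

  max_hr <- apply(snaps, 1L, function(r) if (anyNA(r)) NA_real_ else max(r))
  min_hr <- apply(snaps, 1L, function(r) if (anyNA(r)) NA_real_ else min(r))
  mean24 <- rowMeans(snaps)

  complete <- !is.na(max_hr) & !is.na(all_max)
  out <- data.frame(date = days)
  colnames(snaps) <- sprintf("t%02d", 0:23)
  out <- cbind(out, as.data.frame(snaps))
  out$max <- all_max
  out$min <- all_min
  out$max_hr <- max_hr
  out$min_hr <- min_hr
  out$mean <- (all_max + all_min) / 2
  out$mean_hr <- (max_hr + min_hr) / 2
  out$mean24 <- mean24
  out$interpolated_count <- interp_n
  out$complete <- complete
  attr(out, "n_interpolated") <- sum(interp_n)
  attr(out, "n_excluded") <- sum(!complete)
  class(out) <- c("daily_metrics", "data.frame")
  out
}

#' @export
print.daily_metrics <- function(x, ...) {
  cat(sprintf("<daily_metrics> %d days (%s .. %s), %d excluded, %d interpolated obs\n",
              nrow(x), min(x$date), max(x$date),
              attr(x, "n_excluded") %||% sum(!x$complete),
              attr(x, "n_interpolated") %||% NA))
  NextMethod()
}

#' Write a daily metric table to delimited text
#'
#' @param table a `daily_metrics` data frame.
#' @param path output file path (CSV, ISO-8601 dates).
#' @export
write_metric_table <- function(table, path) {
  out <- as.data.frame(table)
  out$date <- format(out$date, "%Y-%m-%d")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
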