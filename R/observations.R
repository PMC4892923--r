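#' Construct an observation series
#'
#' An observation series is the package's container for timestamped
#' sub-hourly air-temperature records from one station: a data frame with
#' columns `time` (POSIXct, local standard time — the package uses a
#' fixed-offset clock with no daylight-saving shifts), `temp` (degrees C),
#' `missing` and `interpolated` (logical flags).  All temperatures are held
#' internally in degrees Celsius regardless of the unit declared on ingest.
#'
#' @param time POSIXct vector, strictly increasing.
#' @param temp numeric temperatures in degrees C; `NA` where missing.
#' @param missing logical flag per record (recycled).
#' @param interpolated logical flag per record (recycled).
#' @param unit_declared unit of the source data before conversion ("C" or "F").
#' @return A data frame of class `obs_series`.
#' @export
obs_series <- function(time, temp, missing = is.na(temp),
                       interpolated = FALSE, unit_declared = "C") {
  if (!inherits(time, "POSIXct")) {
    time <- as.POSIXct(time, tz = "UTC")
  }
  n <- length(time)
  missing <- rep_len(as.logical(missing), n)
  interpolated <- rep_len(as.logical(interpolated), n)
  temp <- as.numeric(temp)
  if (length(temp) != n) {
    stop_heatclock("`time` and `temp` must have the same length", "heatclock_ingest_error")
  }
  if (n > 1 && any(diff(as.numeric(time)) <= 0)) {
    stop_heatclock("timestamps must be strictly increasing", "heatclock_ingest_error")
  }
  bad <- !missing & (!is.finite(temp) | temp < -90 | temp > 60)
  if (any(bad)) {
    stop_heatclock(
      sprintf("non-missing temperatures must be finite and within -90..60 degC (records: %s)",
              paste(utils::head(which(bad), 10L), collapse = ", ")),
      "heatclock_ingest_error"
    )
  }
  out <- data.frame(time = time, temp = temp, missing = missing,
                    interpolated = interpolated)
  attr(out, "unit_declared") <- unit_declared
  class(out) <- c("obs_series", "data.frame")
  out
}

#' @export
print.obs_series <- function(x, ...) {
  cat(sprintf("<obs_series> %d observations, %s .. %s\n",
              nrow(x),
              format(min(x$time), "%Y-%m-%d %H:%M"),
              format(max(x$time), "%Y-%m-%d %H:%M")))
  cat(sprintf("  missing: %d (%.2f%%)   interpolated: %d\n",
              sum(x$missing), 100 * mean(x$missing), sum(x$interpolated)))
  invisible(x)
}

#' Read station observations from delimited text
#'
#' Parses a delimited text file with a header naming timestamp, temperature
#' and unit columns, converts Fahrenheit records to Celsius, sorts by time,
#' and rejects duplicate timestamps.  Malformed rows are reported with their
#' file line numbers.
#'
#' @param path file path.
#' @param sep field separator (default comma).
#' @return An [obs_series()].
#' @export
read_observations <- function(path, sep = ",") {
  raw <- utils::read.csv(path, sep = sep, strip.white = TRUE,
                         colClasses = "character", check.names = FALSE)
  names(raw) <- tolower(trimws(names(raw)))
  ts_col <- intersect(c("timestamp", "time", "datetime", "date_time"), names(raw))[1]
  temp_col <- intersect(c("temperature", "temp"), names(raw))[1]
  unit_col <- intersect(c("unit", "units"), names(raw))[1]
  if (is.na(ts_col) || is.na(temp_col)) {
    stop_heatclock("header must name timestamp and temperature columns",
                   "heatclock_ingest_error")
  }
  if (nrow(raw) == 0) {
    return(obs_series(as.POSIXct(character(0), tz = "UTC"), numeric(0)))
  }
  lines <- seq_len(nrow(raw)) + 1L  # header is line 1

  time <- as.POSIXct(raw[[ts_col]], tz = "UTC",
                     tryFormats = c("%Y-%m-%d %H:%M:%S", "%Y-%m-%d %H:%M",
                                    "%Y-%m-%dT%H:%M:%S", "%Y-%m-%dT%H:%M",
                                    "%Y-%m-%d"),
                     optional = TRUE)
  bad_ts <- is.na(time)
  if (any(bad_ts)) {
    stop_heatclock(
      sprintf("unparseable timestamps at lines: %s",
              paste(utils::head(lines[bad_ts], 10L), collapse = ", ")),
      "heatclock_ingest_error"
    )
  }

  temp_chr <- trimws(raw[[temp_col]])
  missing <- temp_chr == "" | toupper(temp_chr) %in% c("NA", "M")
  temp <- suppressWarnings(as.numeric(temp_chr))
  bad_temp <- !missing & is.na(temp)
  if (any(bad_temp)) {
    stop_heatclock(
      sprintf("non-numeric temperatures at lines: %s",
              paste(utils::head(lines[bad_temp], 10L), collapse = ", ")),
      "heatclock_ingest_error"
    )
  }

  if (!is.na(unit_col)) {
    unit <- toupper(gsub("[^A-Za-z]", "", raw[[unit_col]]))
    unit[unit == ""] <- "C"
  } else {
    unit <- rep("C", nrow(raw))
  }
  bad_unit <- !unit %in% c("C", "F")
  if (any(bad_unit)) {
    stop_heatclock(
      sprintf("unknown temperature unit at lines: %s",
              paste(utils::head(lines[bad_unit], 10L), collapse = ", ")),
      "heatclock_ingest_error"
    )
  }
  fdeg <- unit == "F" & !missing & !is.na(temp)
  temp[fdeg] <- (temp[fdeg] - 32) * 5 / 9

  ord <- order(time)
  time <- time[ord]; temp <- temp[ord]; missing <- missing[ord]
  dup <- duplicated(time)
  if (any(dup)) {
    stop_heatclock(
      sprintf("duplicate timestamps at lines: %s",
              paste(utils::head(lines[ord][dup], 10L), collapse = ", ")),
      "heatclock_ingest_error"
    )
  }
  temp[missing] <- NA_real_
  obs_series(time, temp, missing = missing,
             unit_declared = if (any(fdeg)) "F" else "C")
}

#' Write an observation series to delimited text
#'
#' @param series an [obs_series()].
#' @param path output file path.
#' @export
write_observations <- function(series, path) {
  out <- data.frame(
    timestamp = format(series$time, "%Y-%m-%d %H:%M:%S"),
    temperature = ifelse(series$missing, "", sprintf("%.10g", series$temp)),
    unit = "C"
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Fill missing observations by linear interpolation in time
#'
#' Interior missing records are linearly interpolated between the nearest
#' non-missing neighbours; missing records before the first (or after the
#' last) non-missing observation are filled with that nearest value.
#' Filled records keep their timestamps and are flagged `interpolated`.
#' The operation is idempotent.
#'
#' @param series an [obs_series()].
#' @return The series with no missing records.
#' @export
interpolate_missing <- function(series) {
  if (!any(series$missing)) {
    return(series)
  }
  ok <- !series$missing
  if (sum(ok) < 2) {
    stop_heatclock("need at least two non-missing observations to interpolate",
                   "heatclock_interpolation_error")
  }
  tnum <- as.numeric(series$time)
  filled <- stats::approx(tnum[ok], series$temp[ok], xout = tnum[!ok],
                          method = "linear", rule = 2)$y
  series$temp[!ok] <- filled
  series$interpolated <- series$interpolated | series$missing
  series$missing <- FALSE
  series
}
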