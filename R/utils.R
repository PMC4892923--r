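# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library code never perturbs the
# user's random stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# One master seed, fixed per-component offsets (temperature = 1, missing
# injection = 2, mortality = 3).  The multiplier decorrelates the streams of
# adjacent master seeds; the result stays inside 32-bit integer range.
child_seed <- function(seed, offset) {
  (abs(as.numeric(seed)) * 101 + offset) %% 2147483647
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_heatclock <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "heatclock_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

is_count <- function(x) length(x) == 1L && is.finite(x) && x == as.integer(x)

# day-of-year as a continuous quantity (1.0 at midnight Jan 1)
frac_doy <- function(time) {
  yr_start <- as.POSIXct(paste0(format(time, "%Y"), "-01-01"), tz = "UTC")
  1 + as.numeric(difftime(time, yr_start, units = "days"))
}
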