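# Percentile-contrast relative risks over the exposure-by-lag grid.

#' Analysis settings for the model grid
#'
#' @param df_per_year degrees of freedom per year for the time smooth
#'   (7 main analysis, 5 sensitivity).
#' @param k_temp temperature-smooth basis dimension (default 4).
#' @param baseline baseline percentile for the relative-risk contrast
#'   (85 main, 90 sensitivity).
#' @param use_covariance if TRUE the CI accounts for the covariance between
#'   the two term predictions; the default (FALSE) combines the two
#'   standard errors in quadrature, the conventional reporting formula.
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(df_per_year = 7, k_temp = 4, baseline = 85,
                       use_covariance = FALSE) {
  if (!df_per_year %in% c(5, 7)) {
    stop_heatclock("df_per_year must be 7 (main) or 5 (sensitivity)",
                   "heatclock_config_error")
  }
  if (!baseline %in% c(85, 90)) {
    stop_heatclock("baseline must be 85 or 90", "heatclock_config_error")
  }
  structure(list(df_per_year = df_per_year, k_temp = k_temp,
                 baseline = baseline, use_covariance = use_covariance),
            class = "model_spec")
}

#' Percentile-contrast relative risk from one fitted model
#'
#' Computes `RR = exp(m99 - m_base)`, where `m99` and `m_base` are the
#' fitted temperature-term contributions at the variable's 99th and
#' baseline (85th or 90th) percentiles, with the 95% confidence interval
#' `exp((m99 - m_base) +/- 1.96 * sqrt(se99^2 + se_base^2))` — the two
#' prediction standard errors combined in quadrature, deliberately ignoring
#' their covariance.  A covariance-aware interval is available via
#' `use_covariance = TRUE` for comparison.  Statistical significance is
#' declared when the interval excludes 1.  No multiple-testing adjustment
#' is applied across grid cells.
#'
#' @param fit a converged [heatgam()] fit.
#' @param percentiles a [compute_percentiles()] result for the same
#'   exposure variable.
#' @param use_covariance use the covariance-aware standard error of the
#'   contrast instead of the quadrature combination.
#' @return A one-row data frame of class `rr_estimate`: `rr`, `ci_lo`,
#'   `ci_hi`, `significant`, `m99`, `m_base`, `se99`, `se_base`, `gcv`,
#'   `phi`, `n`.
#' @export
rr_contrast <- function(fit, percentiles, use_covariance = FALSE) {
  stopifnot(inherits(fit, "heatgam"), inherits(percentiles, "percentile_set"))
  if (percentiles$degenerate) {
    stop_heatclock("degenerate percentiles (p99 == baseline); contrast undefined",
                   "heatclock_degenerate_error")
  }
  if (!fit$converged) {
    stop_heatclock("rr_contrast requires a converged fit", "heatclock_fit_error")
  }
  te <- term_effect(fit, c(percentiles$p99, percentiles$p_base))
  m99 <- te$estimate[1]; m_base <- te$estimate[2]
  se99 <- te$se[1]; se_base <- te$se[2]
  delta <- m99 - m_base
  se <- if (use_covariance) {
    R <- temp_term_rows(fit, c(percentiles$p99, percentiles$p_base))
    r <- R[1, ] - R[2, ]
    idx <- grep("^temp\\.", names(fit$coefficients))
    sqrt(max(0, drop(r %*% fit$cov_scaled[idx, idx] %*% r)))
  } else {
    sqrt(se99^2 + se_base^2)
  }
  ci_lo <- exp(delta - 1.96 * se)
  ci_hi <- exp(delta + 1.96 * se)
  out <- data.frame(rr = exp(delta), ci_lo = ci_lo, ci_hi = ci_hi,
                    significant = ci_lo > 1 | ci_hi < 1,
                    m99 = m99, m_base = m_base,
                    se99 = se99, se_base = se_base,
                    gcv = fit$gcv, phi = fit$phi, n = fit$n)
  class(out) <- c("rr_estimate", "data.frame")
  out
}

#' Fit the full exposure-by-lag model grid
#'
#' Fits one independent quasi-Poisson spline model per grid cell — 31
#' exposure variables (24 hourly snapshots plus 7 daily summary metrics)
#' crossed with lags 0-3, 124 models — and summarises each as a
#' percentile-contrast relative risk.  Cells whose fit fails (degenerate
#' percentiles, rank deficiency, non-convergence) are recorded with a
#' reason and skipped; more than 10% failed cells aborts the run.
#'
#' @param table a `daily_metrics` table from [build_metric_table()].
#' @param deaths data frame with columns `date` and `deaths` (no missing
#'   dates inside the study window).
#' @param spec a [model_spec()].
#' @return A data frame of class `rr_grid`, one row per cell in
#'   deterministic lag-major order, with columns `variable`, `lag`, `rr`,
#'   `ci_lo`, `ci_hi`, `significant`, `gcv`, `phi`, `n`, `p_base`, `p99`,
#'   `converged`, plus the underlying term predictions; attribute
#'   `failures` lists skipped cells with reasons.
#' @examples
#' city <- simulate_city(sim_config(years = 2, seed = 7))
#' grid <- run_grid(city$metrics, city$deaths, model_spec(df_per_year = 5))
#' head(rank_cells(grid)$ranked)
#' @export
run_grid <- function(table, deaths, spec = model_spec()) {
  stopifnot(inherits(spec, "model_spec"))
  cells <- enumerate_exposures(table, baseline = spec$baseline)
  years <- max(1L, round(nrow(deaths) / 365.25))
  k_time <- as.integer(round(years * spec$df_per_year))

  rows <- vector("list", length(cells))
  failures <- list()
  for (i in seq_along(cells)) {
    cell <- cells[[i]]
    base_row <- data.frame(variable = cell$variable, lag = cell$lag,
                           rr = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                           significant = NA, m99 = NA_real_, m_base = NA_real_,
                           se99 = NA_real_, se_base = NA_real_,
                           gcv = NA_real_, phi = NA_real_, n = NA_integer_,
                           p_base = cell$percentiles$p_base,
                           p99 = cell$percentiles$p99,
                           converged = FALSE)
    res <- tryCatch({
      exposure <- data.frame(date = table$date,
                             value = ifelse(table$complete, table[[cell$variable]], NA))
      al <- lag_align(exposure, cell$lag, deaths)
      fit <- heatgam(al$deaths, al$exposure, al$time_index,
                     k_time = k_time, k_temp = spec$k_temp)
      if (!fit$converged) {
        stop_heatclock("fit did not converge", "heatclock_fit_error")
      }
      est <- rr_contrast(fit, cell$percentiles,
                         use_covariance = spec$use_covariance)
      row <- base_row
      row[names(est)] <- est
      row$converged <- TRUE
      row
    }, heatclock_error = function(e) {
      failures[[length(failures) + 1L]] <<- list(variable = cell$variable,
                                                 lag = cell$lag,
                                                 reason = conditionMessage(e))
      base_row
    })
    rows[[i]] <- res
  }
  out <- do.call(rbind, rows)
  if (length(failures) > 0.1 * length(cells)) {
    stop_heatclock(sprintf("%d of %d grid cells failed to fit",
                           length(failures), length(cells)),
                   "heatclock_grid_error")
  }
  attr(out, "failures") <- failures
  attr(out, "spec") <- spec
  class(out) <- c("rr_grid", "data.frame")
  out
}

#' @export
print.rr_grid <- function(x, ...) {
  sp <- attr(x, "spec")
  cat(sprintf("<rr_grid> %d cells (baseline p%d, %d df/year); %d significant, %d failed\n",
              nrow(x), sp$baseline %||% NA, sp$df_per_year %||% NA,
              sum(x$significant, na.rm = TRUE), length(attr(x, "failures"))))
  cat("Top cells by RR:\n")
  r <- rank_cells(x)$ranked
  print(utils::head(as.data.frame(r)[, c("variable", "lag", "rr", "ci_lo",
                                         "ci_hi", "significant", "gcv")], 5L),
        row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
`[.rr_grid` <- function(x, ...) {
  out <- NextMethod()
  # subsets are plain data frames; the grid class implies the full cell set
  if (is.data.frame(out)) class(out) <- setdiff(class(out), "rr_grid")
  out
}

#' Rank grid cells by relative risk
#'
#' Cells are ordered by decreasing RR, with ties broken by lower GCV, then
#' by (lag, variable order).  The minimum-GCV cell is reported separately:
#' the best-fitting model and the largest estimated effect need not
#' coincide, because the RR uses only the two contrast percentiles whereas
#' GCV reflects fit across the whole temperature distribution.
#'
#' @param estimates an `rr_grid` (or data frame of `rr_estimate` rows).
#' @return A list of class `rr_ranking`: `ranked` (the reordered table),
#'   `top` (maximum-RR cell) and `min_gcv` (minimum-GCV cell).
#' @export
rank_cells <- function(estimates) {
  df <- as.data.frame(estimates)
  if (nrow(df) == 0) {
    stop_heatclock("empty estimate list", "heatclock_grid_error")
  }
  var_order <- match(df$variable, exposure_variables())
  ok <- !is.na(df$rr)
  ord <- order(-df$rr, df$gcv, df$lag, var_order, na.last = TRUE)
  ranked <- df[ord, , drop = FALSE]
  gx <- which(ok & df$gcv == min(df$gcv[ok], na.rm = TRUE))[1]
  structure(list(ranked = ranked,
                 top = ranked[1, , drop = FALSE],
                 min_gcv = df[gx, , drop = FALSE]),
            class = "rr_ranking")
}

#' @export
print.rr_ranking <- function(x, ...) {
  cat("Maximum-RR cell:\n")
  print(x$top[, c("variable", "lag", "rr", "ci_lo", "ci_hi", "gcv")],
        row.names = FALSE, digits = 4)
  cat("Minimum-GCV cell:\n")
  print(x$min_gcv[, c("variable", "lag", "rr", "ci_lo", "ci_hi", "gcv")],
        row.names = FALSE, digits = 4)
  invisible(x)
}

#' Plot relative risks by hour and lag
#'
#' Line plot of the hourly-variable RRs against observation hour, one line
#' per lag, with the seven summary metrics omitted (they have no natural
#' hour).
#'
#' @param x an `rr_grid`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.rr_grid <- function(x, ...) {
  hourly <- x[grepl("^t\\d\\d$", x$variable), ]
  hour <- as.integer(sub("^t", "", hourly$variable))
  m <- matrix(NA_real_, 24, 4)
  m[cbind(hour + 1L, hourly$lag + 1L)] <- hourly$rr
  graphics::matplot(0:23, m, type = "l", lty = 1:4, col = 1:4,
                    xlab = "observation hour (LST)", ylab = "relative risk",
                    ...)
  graphics::abline(h = 1, col = "grey")
  graphics::legend("topright", legend = paste("lag", 0:3), lty = 1:4,
                   col = 1:4, bty = "n")
  invisible(x)
}

#' Write an RR grid to delimited text
#'
#' @param grid an `rr_grid`.
#' @param path output file path.
#' @export
write_rr_grid <- function(grid, path) {
  utils::write.csv(as.data.frame(grid), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
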