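# Percentile-contrast relative risks, CIs, and the 124-cell grid.

test_that("the RR/CI formula reproduces hand arithmetic exactly", {
  # linear term effect with controlled slope and variance: contrast 0.05,
  # se99 = se_base = 0.01 (t85 = -1, t99 = +1, centred at 0)
  fit <- fake_linear_fit(beta_temp = 0.025, var_temp = 1e-4)
  est <- rr_contrast(fit, fake_percentiles(-1, 1))
  expect_equal(est$m99 - est$m_base, 0.05, tolerance = 1e-12)
  expect_equal(est$se99, 0.01, tolerance = 1e-12)
  expect_equal(est$se_base, 0.01, tolerance = 1e-12)
  # oracle: exp(0.05 +/- 1.96 * sqrt(0.0001 + 0.0001))
  expect_equal(est$rr, exp(0.05), tolerance = 1e-12)
  expect_equal(est$ci_lo, exp(0.05 - 1.96 * sqrt(2e-4)), tolerance = 1e-12)
  expect_equal(est$ci_hi, exp(0.05 + 1.96 * sqrt(2e-4)), tolerance = 1e-12)
  expect_equal(round(est$rr, 5), 1.05127)
  expect_equal(round(est$ci_lo, 5), 1.02253)
  expect_equal(round(est$ci_hi, 5), 1.08082)
  expect_true(est$significant)
})

test_that("a null contrast gives RR 1 with a log-symmetric CI", {
  fit <- fake_linear_fit(beta_temp = 0, var_temp = 1e-4)
  est <- rr_contrast(fit, fake_percentiles(-1, 1))
  expect_equal(est$rr, 1)
  expect_equal(log(est$ci_hi), -log(est$ci_lo), tolerance = 1e-12)
  expect_false(est$significant)
})

test_that("a term difference of ln(1.051) yields RR 1.051", {
  fit <- fake_linear_fit(beta_temp = log(1.051) / 2, var_temp = 1e-4)
  est <- rr_contrast(fit, fake_percentiles(-1, 1))
  expect_equal(est$rr, 1.051, tolerance = 1e-12)
})

test_that("degenerate percentiles are refused", {
  fit <- fake_linear_fit(0.02, 1e-4)
  expect_error(rr_contrast(fit, fake_percentiles(1, 1)),
               class = "heatclock_degenerate_error")
})

test_that("quadrature CI agrees with a parametric bootstrap within 20% of width", {
  fit <- small_fit()
  ps <- compute_percentiles(small_city()$metrics$t15)
  est <- rr_contrast(fit, ps)

  # oracle: resample coefficients from the fitted covariance, recompute the
  # contrast for each draw, take the percentile interval
  idx <- grep("^temp\\.", names(fit$coefficients))
  V <- fit$cov_scaled[idx, idx]
  R <- heatclock:::temp_term_rows(fit, c(ps$p99, ps$p_base))
  r <- R[1, ] - R[2, ]
  set.seed(42)
  L <- chol(V)
  draws <- matrix(rnorm(1000 * length(idx)), 1000) %*% L
  deltas <- drop(draws %*% r) + (est$m99 - est$m_base)
  boot_ci <- exp(quantile(deltas, c(0.025, 0.975), type = 7))

  width_eq3 <- est$ci_hi - est$ci_lo
  width_boot <- unname(boot_ci[2] - boot_ci[1])
  expect_lt(abs(width_eq3 - width_boot), 0.2 * width_boot)
  # the quadrature interval ignores the (positive) covariance between the
  # two predictions, so it should not be narrower than the bootstrap
  expect_gt(width_eq3, 0.8 * width_boot)
})

test_that("covariance-aware interval is no wider than the quadrature interval", {
  fit <- small_fit()
  ps <- compute_percentiles(small_city()$metrics$t15)
  q <- rr_contrast(fit, ps)
  cv <- rr_contrast(fit, ps, use_covariance = TRUE)
  expect_equal(cv$rr, q$rr)
  expect_lte(cv$ci_hi - cv$ci_lo, q$ci_hi - q$ci_lo)
})

test_that("the grid yields 124 ordered estimates on a complete synthetic city", {
  city <- small_city()
  grid <- run_grid(city$metrics, city$deaths, model_spec(df_per_year = 5))
  expect_s3_class(grid, "rr_grid")
  expect_equal(nrow(grid), 124)
  expect_equal(sum(grid$converged), 124)
  expect_true(all(grid$ci_lo <= grid$rr & grid$rr <= grid$ci_hi))
  expect_true(all(grid$rr > 0))
  expect_equal(grid$significant, grid$ci_lo > 1 | grid$ci_hi < 1)
  # deterministic lag-major ordering
  expect_equal(grid$lag, rep(0:3, each = 31))
  expect_equal(grid$variable[1:24], sprintf("t%02d", 0:23))
  expect_equal(grid$variable[25:31], c("max", "max_hr", "min", "min_hr",
                                       "mean", "mean_hr", "mean24"))
})

test_that("ranking is rr-descending with GCV tie-break and a separate min-GCV report", {
  df <- data.frame(variable = c("t01", "t02", "t03"), lag = c(0L, 0L, 1L),
                   rr = c(1.05, 1.05, 1.02), gcv = c(12, 10, 1),
                   ci_lo = 1, ci_hi = 1.1, significant = TRUE)
  rk <- rank_cells(df)
  expect_equal(rk$ranked$variable, c("t02", "t01", "t03"))  # gcv 10 first
  expect_equal(rk$top$variable, "t02")
  expect_equal(rk$min_gcv$variable, "t03")  # need not equal the top-RR cell
  single <- rank_cells(df[1, ])
  expect_equal(single$top$variable, "t01")
  expect_equal(single$min_gcv$variable, "t01")
})

test_that("grid failures are recorded and tolerated up to the 10% policy", {
  city <- small_city()
  tab <- city$metrics
  # constant exposure column -> degenerate percentiles for those 4 cells
  tab$mean24 <- 15
  grid <- run_grid(tab, city$deaths, model_spec(df_per_year = 5))
  fails <- attr(grid, "failures")
  expect_equal(length(fails), 4)
  expect_true(all(is.na(grid$rr[grid$variable == "mean24"])))
  expect_equal(sum(grid$converged), 120)
})
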