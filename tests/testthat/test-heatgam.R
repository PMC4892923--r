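# The fixed-df spline basis and the quasi-Poisson IRLS engine.

test_that("basis has k full-rank columns spanning constants and linear functions", {
  set.seed(1)
  x <- sort(runif(100, 0, 10))
  for (k in c(2, 3, 4, 6, 10)) {
    B <- spline_basis(x, k)
    expect_equal(ncol(B), k)
    # oracle: singular-value rank
    expect_equal(sum(svd(B)$d > 1e-8), k, info = paste("k =", k))
    # constants and linear functions lie in the span
    for (target in list(rep(1, 100), x)) {
      resid <- target - B %*% qr.solve(B, target)
      expect_lt(max(abs(resid)), 1e-8)
    }
  }
  expect_error(spline_basis(x, 1), class = "heatclock_basis_error")
  expect_error(spline_basis(rep(1:3, 10), 4), class = "heatclock_basis_error")
})

test_that("k = 2 reproduces the ordinary log-linear GLM", {
  set.seed(2)
  n <- 300
  x <- runif(n, 0, 30)
  ti <- seq_len(n)
  y <- rpois(n, exp(1 + 0.03 * x))
  fit <- heatgam(y, x, ti, k_time = 2, k_temp = 2)
  ref <- glm(y ~ ti + x, family = poisson())
  expect_equal(unname(fit$fitted.values), unname(fitted(ref)), tolerance = 1e-6)
})

test_that("a noiseless quadratic response is fitted exactly with k_temp = 4", {
  set.seed(3)
  x <- runif(200, -2, 2)
  mu <- exp(0.5 + 0.3 * x - 0.2 * x^2)
  # "counts" on the noiseless mean: the quadratic lies in the cubic span
  fit <- heatgam(mu, x, seq_along(x), k_time = 2, k_temp = 4)
  expect_lt(fit$deviance, 1e-8)
})

test_that("degenerate intercept-only and two-group fits match closed forms", {
  # intercept-only design on counts {1,2,3}: exp(intercept) is the Poisson
  # MLE of the mean, exactly 2
  irls <- heatclock:::qp_irls(matrix(1, 3, 1), c(1, 2, 3),
                              epsilon = 1e-13)
  expect_true(irls$converged)
  expect_equal(exp(irls$beta[[1]]), 2, tolerance = 1e-9)

  # two-level exposure, no time smooth: fitted log rate ratio = log 4
  y2 <- rep(c(2, 8), each = 30)
  x2 <- rep(c(0, 1), each = 30)
  # constant-free time index is impossible; use a 2-col time basis on a
  # balanced index so its coefficient is estimable but unneeded
  fit2 <- heatgam(y2, x2, rep(seq_len(30), 2), k_time = 2, k_temp = 2)
  te <- term_effect(fit2, c(1, 0))
  expect_equal(te$estimate[1] - te$estimate[2], log(4), tolerance = 1e-6)
})

test_that("IRLS matches an independent quasi-Poisson implementation on the same design", {
  city <- small_city()
  fit <- small_fit()
  X <- fit$design
  ref <- glm(fit$y ~ X - 1, family = quasipoisson())
  expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(fit$phi, summary(ref)$dispersion, tolerance = 1e-6)
  expect_equal(unname(sqrt(diag(fit$cov_scaled))),
               unname(summary(ref)$coefficients[, 2]), tolerance = 1e-5)
})

test_that("coefficients maximize the Poisson likelihood (BFGS oracle)", {
  # independent generic-optimizer maximization on small random datasets
  set.seed(11)
  for (rep in 1:5) {
    n <- 200
    x <- runif(n, 0, 25)
    ti <- seq_len(n)
    y <- rpois(n, exp(1.2 + 0.02 * x + 0.2 * sin(ti / 30)))
    fit <- heatgam(y, x, ti, k_time = 4, k_temp = 3)
    X <- fit$design
    nll <- function(b) sum(exp(X %*% b)) - sum(y * (X %*% b))
    gr <- function(b) drop(crossprod(X, exp(X %*% b) - y))
    opt <- optim(c(log(mean(y)), rep(0, ncol(X) - 1)), nll, gr,
                 method = "BFGS",
                 control = list(maxit = 1000, reltol = 1e-15))
    expect_lt(max(abs(opt$par - unname(fit$coefficients))), 1e-6)
  }
})

test_that("fitted means sum to the observed total deaths", {
  fit <- small_fit()
  expect_equal(sum(fit$fitted.values), sum(fit$y),
               tolerance = 1e-6 * sum(fit$y))
})

test_that("dispersion is near 1 when the generator is Poisson", {
  cfg <- sim_config(years = 10, overdispersion = 1, seed = 19)
  city <- simulate_city(cfg)
  al <- lag_align(data.frame(date = city$metrics$date,
                             value = city$metrics$t15),
                  0, city$deaths)
  fit <- heatgam(al$deaths, al$exposure, al$time_index, df_per_year = 5)
  expect_gt(fit$phi, 0.9)
  expect_lt(fit$phi, 1.1)
})

test_that("GCV follows n * D / (n - edf)^2 and is monotone in deviance", {
  fit <- small_fit()
  expect_equal(gcv_score(fit),
               fit$n * fit$deviance / (fit$n - fit$edf)^2)
  expect_equal(gcv_score(fit), fit$gcv)
  # zero deviance -> zero score
  x <- runif(50)
  mu <- exp(1 + 0.1 * x)
  perfect <- heatgam(mu, x, seq_len(50), k_time = 2, k_temp = 2)
  expect_lt(perfect$deviance, 1e-6)
  expect_lt(gcv_score(perfect), 1e-8)
})

test_that("term effects match a delta-method oracle built from the covariance", {
  fit <- small_fit()
  pts <- c(10, 20, 28)
  te <- term_effect(fit, pts)
  idx <- grep("^temp\\.", names(fit$coefficients))
  V <- fit$cov_scaled[idx, idx]
  for (i in seq_along(pts)) {
    # oracle: finite-difference gradient of the term prediction in the
    # coefficients, times the scaled covariance
    h <- 1e-6
    grad <- vapply(seq_along(idx), function(j) {
      b <- fit$coefficients
      bp <- b; bp[idx[j]] <- bp[idx[j]] + h
      bm <- b; bm[idx[j]] <- bm[idx[j]] - h
      fit2p <- fit; fit2p$coefficients <- bp
      fit2m <- fit; fit2m$coefficients <- bm
      (term_effect(fit2p, pts[i])$estimate -
         term_effect(fit2m, pts[i])$estimate) / (2 * h)
    }, 0)
    expect_equal(te$se[i], sqrt(drop(grad %*% V %*% grad)), tolerance = 1e-6)
  }
  # a point contrasted with itself is exactly null
  expect_equal(te$estimate[1] - te$estimate[1], 0)
  # linear k_temp = 2 fit: difference equals slope times distance
  al <- with(small_city(), lag_align(data.frame(date = metrics$date,
                                                value = metrics$t15),
                                     0, deaths))
  lin <- heatgam(al$deaths, al$exposure, al$time_index, k_time = 10, k_temp = 2)
  slope <- unname(lin$coefficients["temp.1"])
  te2 <- term_effect(lin, c(25, 20))
  expect_equal(te2$estimate[1] - te2$estimate[2], slope * 5, tolerance = 1e-10)
  expect_warning(term_effect(lin, 99), "extrapolat")
})

test_that("the RR point estimate is invariant to the centering constant", {
  fit <- small_fit()
  ps <- compute_percentiles(small_city()$metrics$t15)
  base <- rr_contrast(fit, ps)
  shifted <- fit
  shifted$temp_centering <- fit$temp_centering + 0.37
  sh <- rr_contrast(shifted, ps)
  # the constant cancels in the difference of term predictions
  expect_equal(sh$rr, base$rr, tolerance = 1e-12)
  # the covariance-aware CI depends only on the contrast row, so it is
  # invariant too; the quadrature CI combines point-wise standard errors
  # and therefore inherits the (conventional, sum-to-zero) centering
  cv_base <- rr_contrast(fit, ps, use_covariance = TRUE)
  cv_sh <- rr_contrast(shifted, ps, use_covariance = TRUE)
  expect_equal(cv_sh$ci_lo, cv_base$ci_lo, tolerance = 1e-12)
  expect_equal(cv_sh$ci_hi, cv_base$ci_hi, tolerance = 1e-12)
})

test_that("methods behave: print, summary, residuals, predict, simulate", {
  fit <- small_fit()
  expect_output(print(fit), "Quasi-Poisson")
  expect_output(print(summary(fit)), "Coefficients")
  expect_length(coef(fit), fit$edf)
  expect_equal(length(residuals(fit, "pearson")), fit$n)
  expect_equal(sum(residuals(fit, "deviance")^2), fit$deviance,
               tolerance = 1e-8)
  pr <- predict(fit, newdata = list(time_index = 1:5,
                                    exposure = c(10, 12, 14, 16, 18)),
                type = "response")
  expect_true(all(is.finite(pr) & pr > 0))
  sims <- simulate(fit, nsim = 3, seed = 5)
  expect_equal(dim(sims), c(fit$n, 3))
  expect_identical(sims, simulate(fit, nsim = 3, seed = 5))
})
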