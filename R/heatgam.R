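# Quasi-Poisson regression with fixed-df spline terms, fitted by IRLS.

#' Fixed-df regression spline basis
#'
#' Returns a k-column spline basis spanning constants and linear functions
#' plus k - 2 curvature functions, realised as a cubic regression spline: a
#' B-spline basis of degree `min(3, k - 1)` with `k - 1 - degree` interior
#' knots at quantiles of `x`.  With k = 2 the basis is exactly
#' `[1, x]` (a fit using it reproduces the ordinary log-linear model); with
#' k = 4 it spans all cubic polynomials.  The basis has full column rank on
#' inputs with at least k distinct values; the constant direction (the
#' columns sum to one) is identified and dropped when the basis enters a
#' model alongside an intercept.
#'
#' @param x numeric vector.
#' @param k basis dimension (>= 2); the smooth contributes k - 1 model
#'   degrees of freedom once the constant is absorbed by the intercept.
#' @return Numeric matrix with k columns and attribute `basis_spec`
#'   (degree, interior knots, boundary knots) for later evaluation at new
#'   points.
#' @export
spline_basis <- function(x, k) {
  if (!is_count(k) || k < 2) {
    stop_heatclock("k must be an integer >= 2", "heatclock_basis_error")
  }
  ux <- unique(x[is.finite(x)])
  if (length(ux) < k) {
    stop_heatclock(sprintf("basis dimension k = %d exceeds the %d distinct values of x",
                           k, length(ux)),
                   "heatclock_basis_error")
  }
  if (k == 2) {
    B <- cbind(1, x)
    spec <- list(k = 2L, degree = 1L, interior = numeric(0),
                 boundary = range(ux), linear = TRUE)
  } else {
    degree <- min(3L, k - 1L)
    n_int <- k - 1L - degree
    interior <- if (n_int > 0) {
      unname(quantile(x, probs = seq_len(n_int) / (n_int + 1), type = 7))
    } else {
      numeric(0)
    }
    boundary <- range(ux)
    spec <- list(k = as.integer(k), degree = degree, interior = interior,
                 boundary = boundary, linear = FALSE)
    B <- eval_basis(spec, x)
  }
  attr(B, "basis_spec") <- spec
  B
}

# evaluate a basis_spec at new points; values outside the boundary knots of
# a B-spline basis evaluate to zero rows (callers warn on extrapolation)
eval_basis <- function(spec, x) {
  if (isTRUE(spec$linear)) {
    return(cbind(1, x))
  }
  knots <- c(rep(spec$boundary[1], spec$degree + 1), spec$interior,
             rep(spec$boundary[2], spec$degree + 1))
  splines::splineDesign(knots, x, ord = spec$degree + 1, outer.ok = TRUE)
}

poisson_deviance <- function(y, mu) {
  term <- ifelse(y > 0, y * log(y / mu), 0)
  2 * sum(term - (y - mu))
}

# IRLS core: Fisher scoring for the Poisson log-link on an arbitrary design,
# with step halving on deviance increase.  Returns the Poisson ML solution
# (point estimates are identical under quasi-Poisson).
qp_irls <- function(X, y, epsilon = 1e-9, maxit = 50L) {
  mu <- y + 0.5
  eta <- log(mu)
  dev <- poisson_deviance(y, mu)
  beta <- NULL
  converged <- FALSE
  rank_ok <- TRUE
  iter <- 0L
  for (iter in seq_len(maxit)) {
    w <- mu
    z <- eta + (y - mu) / mu
    wls <- lm.wfit(X, z, w)
    if (any(is.na(wls$coefficients))) {
      rank_ok <- FALSE
      break
    }
    beta_new <- wls$coefficients
    step <- 1
    repeat {
      b <- if (is.null(beta)) beta_new else beta + step * (beta_new - beta)
      eta_new <- drop(X %*% b)
      mu_new <- exp(eta_new)
      dev_new <- poisson_deviance(y, mu_new)
      if (is.finite(dev_new) && (is.null(beta) || dev_new <= dev + 1e-8)) break
      step <- step / 2
      if (step < 1e-10) break
    }
    beta <- b
    eta <- eta_new
    mu <- mu_new
    if (abs(dev - dev_new) / (abs(dev_new) + 0.1) < epsilon) {
      dev <- dev_new
      converged <- TRUE
      break
    }
    dev <- dev_new
  }
  list(beta = beta, mu = mu, eta = eta, deviance = dev,
       iterations = iter, converged = converged, rank_ok = rank_ok)
}

#' Fit a quasi-Poisson spline model of daily mortality
#'
#' Fits the log-link count-regression model
#' `log E(deaths) = s(time, k_time) + s(exposure, k_temp)` by iteratively
#' reweighted least squares, where both smooths are fixed-df regression
#' splines ([spline_basis()]); no penalisation is applied, so the model
#' degrees of freedom equal the number of identifiable columns
#' (`1 + (k_time - 1) + (k_temp - 1)`).  The quasi-Poisson family keeps the
#' Poisson point estimates and scales the coefficient covariance by the
#' Pearson dispersion `phi = sum((y - mu)^2 / mu) / (n - edf)`.
#'
#' The time smooth absorbs long-term trends and seasonality in mortality;
#' `k_time` is conventionally `years * df_per_year` with 7 df/year for the
#' main analysis and 5 df/year as a sensitivity analysis.  The temperature
#' smooth is small (`k_temp = 4`) so the exposure-response is flexible but
#' not wiggly.
#'
#' @param counts non-negative integer daily death counts.
#' @param exposure numeric daily exposure values aligned with `counts`
#'   (see [lag_align()]).
#' @param time_index integer day counter (default `seq_along(counts)`).
#' @param k_time basis dimension of the time smooth; defaults to
#'   `years * df_per_year`.
#' @param k_temp basis dimension of the temperature smooth (default 4).
#' @param df_per_year degrees of freedom per year used when `k_time` is not
#'   given (7 main, 5 sensitivity).
#' @param years number of years spanned; inferred from the length of the
#'   series when not given.
#' @param control list: `epsilon` (relative deviance convergence tolerance,
#'   default 1e-9) and `maxit` (default 50).
#' @return An object of class `heatgam`: coefficients, dispersion-scaled
#'   covariance, fixed effective df, quasi-deviance, Pearson dispersion,
#'   GCV score `n * D / (n - edf)^2`, convergence flag, the model matrix
#'   (`design`), and the fitted basis specifications needed by
#'   [term_effect()] and [predict.heatgam()].
#' @examples
#' city <- simulate_city(sim_config(years = 2, seed = 7))
#' al <- lag_align(data.frame(date = city$metrics$date,
#'                            value = city$metrics$t15),
#'                 lag = 0, deaths = city$deaths)
#' fit <- heatgam(al$deaths, al$exposure, al$time_index, df_per_year = 5)
#' fit
#' @export
heatgam <- function(counts, exposure, time_index = seq_along(counts),
                    k_time = NULL, k_temp = 4, df_per_year = 7,
                    years = NULL, control = list()) {
  y <- as.numeric(counts)
  n <- length(y)
  if (any(!is.finite(y)) || any(y < 0)) {
    stop_heatclock("counts must be finite and non-negative", "heatclock_fit_error")
  }
  if (length(exposure) != n || length(time_index) != n) {
    stop_heatclock("counts, exposure and time_index must have equal length",
                   "heatclock_fit_error")
  }
  if (is.null(k_time)) {
    if (is.null(years)) years <- max(1L, round(n / 365.25))
    k_time <- max(2L, as.integer(round(years * df_per_year)))
  }
  eps <- control$epsilon %||% 1e-9
  maxit <- control$maxit %||% 50L

  Bt <- spline_basis(time_index, k_time)
  Bx <- spline_basis(exposure, k_temp)
  spec_t <- attr(Bt, "basis_spec")
  spec_x <- attr(Bx, "basis_spec")

  # drop each smooth's constant direction, centre the remaining columns so
  # term contributions are expressed relative to the data mean
  Zt <- Bt[, -1L, drop = FALSE]
  Zx <- Bx[, -1L, drop = FALSE]
  ct <- colMeans(Zt)
  cx <- colMeans(Zx)
  Zt <- sweep(Zt, 2L, ct)
  Zx <- sweep(Zx, 2L, cx)
  X <- cbind(1, Zt, Zx)
  p_t <- ncol(Zt)
  p_x <- ncol(Zx)
  colnames(X) <- c("(Intercept)",
                   paste0("time.", seq_len(p_t)),
                   paste0("temp.", seq_len(p_x)))

  irls <- qp_irls(X, y, epsilon = eps, maxit = maxit)
  beta <- irls$beta
  mu <- irls$mu
  eta <- irls$eta
  dev <- irls$deviance
  converged <- irls$converged
  rank_ok <- irls$rank_ok

  edf <- ncol(X)
  pearson <- sum((y - mu)^2 / mu)
  phi <- pearson / (n - edf)
  A <- crossprod(X * sqrt(mu))
  cov_unscaled <- tryCatch(chol2inv(chol(A)), error = function(e) {
    rank_ok <<- FALSE
    matrix(NA_real_, ncol(X), ncol(X))
  })
  cov_scaled <- phi * cov_unscaled
  dimnames(cov_scaled) <- dimnames(cov_unscaled) <- list(colnames(X), colnames(X))
  gcv <- n * dev / (n - edf)^2

  structure(list(
    coefficients = if (is.null(beta)) rep(NA_real_, ncol(X)) else setNames(beta, colnames(X)),
    cov_scaled = cov_scaled,
    cov_unscaled = cov_unscaled,
    fitted.values = mu,
    linear.predictors = eta,
    design = X,
    y = y,
    n = n,
    edf = edf,
    deviance = dev,
    phi = phi,
    gcv = gcv,
    converged = converged && rank_ok,
    rank_deficient = !rank_ok,
    iterations = irls$iterations,
    k_time = k_time,
    k_temp = k_temp,
    time_spec = spec_t,
    temp_spec = spec_x,
    time_centering = ct,
    temp_centering = cx,
    temp_range = range(exposure),
    time_range = range(time_index),
    call = match.call()
  ), class = "heatgam")
}

# centred temperature-basis rows for new exposure values
temp_term_rows <- function(fit, temp_value) {
  r <- fit$temp_range
  if (any(temp_value < r[1] | temp_value > r[2])) {
    warning("temperature value outside the observed exposure range; extrapolating")
  }
  B <- eval_basis(fit$temp_spec, temp_value)[, -1L, drop = FALSE]
  sweep(B, 2L, fit$temp_centering)
}

#' Temperature-term contribution and standard error at a temperature
#'
#' Evaluates the fitted temperature smooth (centred, i.e. relative to the
#' data-mean contribution) at the supplied temperature(s), with the
#' delta-method standard error from the dispersion-scaled coefficient
#' covariance.  The centring constant cancels in any difference between two
#' temperatures, so percentile contrasts do not depend on it.
#'
#' @param fit a converged [heatgam()] fit.
#' @param temp_value numeric temperature(s), degrees C.  Values outside the
#'   observed exposure range trigger an extrapolation warning but are still
#'   computed.
#' @return A data frame with columns `estimate` (log-rate contribution) and
#'   `se`.
#' @export
term_effect <- function(fit, temp_value) {
  stopifnot(inherits(fit, "heatgam"))
  if (!fit$converged) {
    stop_heatclock("term_effect requires a converged fit", "heatclock_fit_error")
  }
  R <- temp_term_rows(fit, temp_value)
  idx <- grep("^temp\\.", names(fit$coefficients))
  beta <- fit$coefficients[idx]
  V <- fit$cov_scaled[idx, idx, drop = FALSE]
  est <- drop(R %*% beta)
  se <- sqrt(pmax(0, rowSums((R %*% V) * R)))
  data.frame(estimate = est, se = se)
}

#' Generalized cross-validation score of a fit
#'
#' `GCV = n * D / (n - edf)^2` with D the quasi-deviance — the conventional
#' diagnostic form for an unpenalised quasi-likelihood fit.  Lower scores
#' indicate better fit; scores are comparable across models fitted to the
#' same response.
#'
#' @param fit a converged [heatgam()] fit.
#' @return The GCV score (non-negative).
#' @export
gcv_score <- function(fit) {
  stopifnot(inherits(fit, "heatgam"))
  if (fit$edf >= fit$n) {
    stop_heatclock("GCV undefined: edf >= n", "heatclock_fit_error")
  }
  fit$n * fit$deviance / (fit$n - fit$edf)^2
}

#' @export
print.heatgam <- function(x, ...) {
  cat("Quasi-Poisson spline model (fixed-df)\n")
  cat(sprintf("  n = %d, k_time = %d, k_temp = %d, edf = %d\n",
              x$n, x$k_time, x$k_temp, x$edf))
  cat(sprintf("  deviance = %.2f, dispersion phi = %.3f, GCV = %.4f\n",
              x$deviance, x$phi, x$gcv))
  if (!x$converged) cat("  ** fit did not converge **\n")
  invisible(x)
}

#' @export
summary.heatgam <- function(object, ...) {
  se <- sqrt(diag(object$cov_scaled))
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = se,
               `t value` = object$coefficients / se)
  structure(list(fit = object, coefficients = tab),
            class = "summary.heatgam")
}

#' @export
print.summary.heatgam <- function(x, ...) {
  print(x$fit)
  cat("\nCoefficients:\n")
  stats::printCoefmat(x$coefficients, ...)
  invisible(x)
}

#' @export
coef.heatgam <- function(object, ...) object$coefficients

#' @export
fitted.heatgam <- function(object, ...) object$fitted.values

#' @export
residuals.heatgam <- function(object,
                              type = c("deviance", "pearson", "response"),
                              ...) {
  type <- match.arg(type)
  y <- object$y
  mu <- object$fitted.values
  switch(type,
    response = y - mu,
    pearson = (y - mu) / sqrt(mu),
    deviance = {
      d <- 2 * (ifelse(y > 0, y * log(y / mu), 0) - (y - mu))
      sign(y - mu) * sqrt(pmax(0, d))
    }
  )
}

#' Predict from a fitted heat-mortality model
#'
#' @param object a [heatgam()] fit.
#' @param newdata optional list or data frame with `time_index` and
#'   `exposure`; defaults to the training data predictions.
#' @param type `"link"` (linear predictor), `"response"` (expected count),
#'   or `"terms"` (centred time and temperature term contributions).
#' @param ... unused.
#' @return Numeric vector, or a two-column matrix for `type = "terms"`.
#' @export
predict.heatgam <- function(object, newdata = NULL,
                            type = c("link", "response", "terms"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    if (type == "link") return(object$linear.predictors)
    if (type == "response") return(object$fitted.values)
    newdata <- list(time_index = NULL, exposure = NULL)
  }
  beta <- object$coefficients
  it <- grep("^time\\.", names(beta))
  ix <- grep("^temp\\.", names(beta))
  tt <- if (!is.null(newdata$time_index)) {
    Bt <- eval_basis(object$time_spec, newdata$time_index)[, -1L, drop = FALSE]
    drop(sweep(Bt, 2L, object$time_centering) %*% beta[it])
  } else {
    NULL
  }
  tx <- if (!is.null(newdata$exposure)) {
    drop(temp_term_rows(object, newdata$exposure) %*% beta[ix])
  } else {
    NULL
  }
  if (type == "terms") {
    return(cbind(time = tt, temp = tx))
  }
  if (is.null(tt) || is.null(tx)) {
    stop_heatclock("newdata must supply both time_index and exposure",
                   "heatclock_fit_error")
  }
  eta <- beta[1L] + tt + tx
  if (type == "response") exp(eta) else eta
}

#' Simulate death counts from a fitted model
#'
#' Draws replicate response vectors from the fitted mean structure using a
#' gamma-Poisson mixture matching the estimated dispersion (`Var = phi *
#' mean`), or plain Poisson when `phi <= 1`.
#'
#' @param object a converged [heatgam()] fit.
#' @param nsim number of replicate series.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return A data frame with `nsim` columns, as [stats::simulate()].
#' @export
simulate.heatgam <- function(object, nsim = 1, seed = NULL, ...) {
  mu <- object$fitted.values
  draw <- function() {
    if (object$phi <= 1) {
      rpois(length(mu), mu)
    } else {
      rnbinom(length(mu), mu = mu, size = mu / (object$phi - 1))
    }
  }
  sims <- if (is.null(seed)) {
    replicate(nsim, draw())
  } else {
    with_seed(seed, replicate(nsim, draw()))
  }
  as.data.frame(sims, col.names = paste0("sim_", seq_len(nsim)))
}

#' Plot the fitted temperature-response curve
#'
#' Draws the centred temperature-term contribution (log scale) across the
#' observed exposure range with a pointwise 95% band (1.96 standard
#' errors).
#'
#' @param x a converged [heatgam()] fit.
#' @param n number of evaluation points.
#' @param ... passed to [graphics::plot()].
#' @export
plot.heatgam <- function(x, n = 200, ...) {
  grid <- seq(x$temp_range[1], x$temp_range[2], length.out = n)
  te <- term_effect(x, grid)
  lo <- te$estimate - 1.96 * te$se
  hi <- te$estimate + 1.96 * te$se
  graphics::plot(grid, te$estimate, type = "l", lwd = 2,
                 ylim = range(lo, hi),
                 xlab = "temperature (degC)",
                 ylab = "log-rate contribution", ...)
  graphics::lines(grid, lo, lty = 2)
  graphics::lines(grid, hi, lty = 2)
  graphics::abline(h = 0, col = "grey")
  invisible(x)
}
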