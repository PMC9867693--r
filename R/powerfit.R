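#' Construct a shifted-power-function fit object
#'
#' Builds a `power_fit` describing the effort-bias curve
#' `y = coef * x^exp - 1` from known parameters, e.g. published estimates;
#' [fit_power()] returns the same class with full least-squares diagnostics.
#'
#' @param coef,exp Curve parameters (the multiplier and the exponent).
#' @param covariance Optional 2x2 parameter covariance matrix.
#' @param se Optional length-2 standard errors (defaults to the covariance
#'   diagonal).
#' @param residual_se,dof,n_points Optional fit diagnostics.
#' @return Object of class `power_fit`.
#' @export
power_fit <- function(coef, exp, covariance = NULL, se = NULL,
                      residual_se = NA_real_, dof = NA_integer_,
                      n_points = NA_integer_) {
  if (is.null(covariance)) covariance <- matrix(0, 2, 2)
  if (is.null(se)) se <- sqrt(pmax(diag(covariance), 0))
  structure(
    list(
      coef = coef, exp = exp,
      se_coef = se[1], se_exp = se[2],
      t_coef = coef / se[1], t_exp = exp / se[2],
      p_coef = NA_real_, p_exp = NA_real_,
      residual_se = residual_se, dof = dof,
      covariance = covariance, converged = TRUE,
      n_points = n_points, iterations = 0L,
      gradient_norm = NA_real_, data = NULL
    ),
    class = "power_fit"
  )
}

power_curve <- function(coef, expo, x) coef * x^expo - 1

#' Fit the shifted power function to duration-bias points
#'
#' Least-squares fit of `y = coef * x^exp - 1` by damped Gauss-Newton
#' (Levenberg-Marquardt) with the analytic Jacobian
#' (`d/dcoef = x^exp`, `d/dexp = coef * x^exp * log(x)`).  Initial values
#' come from the log-log linear regression of `log(y + 1)` on `log(x)` over
#' points with `y + 1 > 0` (exact for noiseless data), falling back to
#' (0.2, 0.3) when fewer than three such points exist.  Standard errors are
#' `residual_se^2 * (J'J)^-1` at the optimum; t statistics are estimate/SE
#' and p values are two-sided from the t distribution on `n - 2` degrees of
#' freedom.
#'
#' @param x_durations Positive durations (minutes).
#' @param y_biases Bias values (each >= -1 in the intended use).
#' @param init Optional starting `c(coef, exp)`.
#' @param max_iter Maximum Levenberg-Marquardt iterations (default 500).
#' @param rel_tol Relative convergence tolerance on the residual sum of
#'   squares and the parameter step (default 1e-10).
#' @return Object of class `power_fit`; `converged = FALSE` flags a fit that
#'   exhausted `max_iter` (a warning is raised, the result is still
#'   returned).
#' @examples
#' x <- 6:200
#' y <- 0.1729 * x^0.2853 - 1
#' fit <- fit_power(x, y)
#' c(fit$coef, fit$exp)
#' @export
fit_power <- function(x_durations, y_biases, init = NULL, max_iter = 500L,
                      rel_tol = 1e-10) {
  x <- as.numeric(x_durations)
  y <- as.numeric(y_biases)
  if (length(x) != length(y)) abort("x and y lengths differ")
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 3) abort("fit_power() needs at least 3 points")
  if (any(x <= 0)) abort("all durations must be positive")

  if (is.null(init)) {
    usable <- y + 1 > 0
    if (sum(usable) >= 3) {
      ll <- lm(log(y[usable] + 1) ~ log(x[usable]))
      init <- c(exp(coef(ll)[[1]]), coef(ll)[[2]])
    } else {
      init <- c(0.2, 0.3)
    }
  }
  theta <- as.numeric(init)
  lx <- log(x)
  rss_of <- function(th) sum((y - power_curve(th[1], th[2], x))^2)

  rss <- rss_of(theta)
  lambda <- 1e-3
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    xe <- x^theta[2]
    r <- y - (theta[1] * xe - 1)
    J <- cbind(xe, theta[1] * xe * lx)
    jtj <- crossprod(J)
    g <- crossprod(J, r)
    step_ok <- FALSE
    for (inner in 1:60) {
      damp <- jtj + lambda * (diag(diag(jtj), 2) + 1e-12 * diag(2))
      delta <- tryCatch(solve(damp, g), error = function(e) NULL)
      if (is.null(delta)) {
        lambda <- lambda * 10
        next
      }
      cand <- theta + as.numeric(delta)
      rss_new <- rss_of(cand)
      if (is.finite(rss_new) && rss_new <= rss) {
        step_rel <- max(abs(delta) / (abs(theta) + 1e-8))
        improved <- rss - rss_new
        theta <- cand
        rss <- rss_new
        lambda <- max(lambda / 10, 1e-12)
        step_ok <- TRUE
        if (improved <= rel_tol * (rss + 1e-300) && step_rel <= sqrt(rel_tol)) {
          converged <- TRUE
        }
        break
      }
      lambda <- lambda * 10
    }
    if (!step_ok) {
      # no downhill step found at any damping: at a (local) optimum
      converged <- TRUE
    }
    if (converged) break
  }
  if (!converged) {
    warn(sprintf("fit_power() did not converge in %d iterations", max_iter))
  }

  xe <- x^theta[2]
  r <- y - (theta[1] * xe - 1)
  J <- cbind(xe, theta[1] * xe * lx)
  jtj <- crossprod(J)
  n <- length(x)
  dof <- n - 2L
  residual_se <- sqrt(sum(r^2) / dof)
  covariance <- tryCatch(
    residual_se^2 * solve(jtj),
    error = function(e) matrix(NA_real_, 2, 2)
  )
  se <- sqrt(pmax(diag(covariance), 0))
  tval <- theta / se
  pval <- pmax(2 * pt(-abs(tval), dof), .Machine$double.xmin)

  structure(
    list(
      coef = theta[1], exp = theta[2],
      se_coef = se[1], se_exp = se[2],
      t_coef = tval[1], t_exp = tval[2],
      p_coef = pval[1], p_exp = pval[2],
      residual_se = residual_se, dof = dof,
      covariance = covariance, converged = converged,
      n_points = n, iterations = iter,
      gradient_norm = sqrt(sum(crossprod(J, r)^2)),
      data = tibble::tibble(x = x, y = y)
    ),
    class = "power_fit"
  )
}

#' @export
print.power_fit <- function(x, ...) {
  cat("Shifted power function  y = coef * x^exp - 1\n")
  cat(sprintf(
    "  coef = %.4f (SE %.4f, t %.3f, p %.3g)\n",
    x$coef, x$se_coef, x$t_coef, x$p_coef
  ))
  cat(sprintf(
    "  exp  = %.4f (SE %.4f, t %.3f, p %.3g)\n",
    x$exp, x$se_exp, x$t_exp, x$p_exp
  ))
  cat(sprintf(
    "  residual SE %.4f on %d degrees of freedom (n = %s, %s)\n",
    x$residual_se, x$dof, x$n_points %||% NA,
    if (isTRUE(x$converged)) "converged" else "NOT converged"
  ))
  invisible(x)
}

#' Predicted bias and completeness at a duration
#'
#' `predict_bias()` evaluates the fitted curve `coef * x^exp - 1`;
#' `completeness_percent()` is `100 * (1 + bias) = 100 * coef * x^exp`, the
#' percentage of the reference richness captured at duration `x` (100% means
#' parity with the reference).
#'
#' @param fit A `power_fit`.
#' @param x Positive duration(s), minutes.
#' @return Numeric vector.
#' @examples
#' fit <- power_fit(coef = 0.1729, exp = 0.2853)
#' round(predict_bias(fit, 60), 2)
#' round(completeness_percent(fit, 60))
#' @export
predict_bias <- function(fit, x) {
  if (any(x <= 0)) abort("duration must be positive")
  power_curve(fit$coef, fit$exp, x)
}

#' @rdname predict_bias
#' @export
completeness_percent <- function(fit, x) {
  100 * (1 + predict_bias(fit, x))
}

#' @export
predict.power_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$x else newdata$x %||% newdata
  predict_bias(object, x)
}

#' Monte-Carlo confidence band for the fitted curve
#'
#' Draws `n_sims` parameter pairs from the bivariate normal centred on the
#' estimates with the fit covariance, evaluates the curve on `x_grid`, and
#' returns pointwise 2.5/97.5 percentiles.  A covariance that is not positive
#' semidefinite is repaired by clipping negative eigenvalues at zero (with a
#' warning).  Fully seeded and reproducible.
#'
#' @param fit A `power_fit` with a finite covariance.
#' @param x_grid Positive durations to evaluate.
#' @param n_sims Number of parameter draws (default 10000).
#' @param seed Integer seed.
#' @param level Confidence level (default 0.95).
#' @return Object of class `curve_band`: tibble (x, fit, lo95, hi95) with
#'   attributes `n_sims` and `seed`.
#' @export
mc_confidence_band <- function(fit, x_grid, n_sims = 10000L, seed = 1L,
                               level = 0.95) {
  if (!isTRUE(fit$converged)) abort("fit did not converge; no band computed")
  sigma <- fit$covariance
  if (any(!is.finite(sigma))) abort("fit covariance is not finite")
  ev <- eigen(sigma, symmetric = TRUE)
  if (any(ev$values < -1e-12)) {
    warn("covariance not positive semidefinite; clipping eigenvalues at 0")
  }
  vals <- pmax(ev$values, 0)
  sigma <- ev$vectors %*% diag(vals, 2) %*% t(ev$vectors)
  draws <- withr::with_seed(
    as.integer(seed),
    MASS::mvrnorm(n_sims, mu = c(fit$coef, fit$exp), Sigma = sigma)
  )
  # curves: n_sims x length(x_grid)
  curves <- draws[, 1] * exp(outer(draws[, 2], log(x_grid))) - 1
  alpha <- (1 - level) / 2
  qs <- apply(curves, 2, quantile, probs = c(alpha, 1 - alpha), names = FALSE)
  band <- tibble::tibble(
    x = x_grid,
    fit = predict_bias(fit, x_grid),
    lo95 = qs[1, ],
    hi95 = qs[2, ]
  )
  structure(band, class = c("curve_band", class(band)),
    n_sims = n_sims, seed = seed, method = "monte_carlo"
  )
}

#' Taylor-expansion (delta-method) confidence band
#'
#' First-order: pointwise variance `g' Sigma g` with gradient
#' `g = (x^exp, coef * x^exp * log x)`.  Second-order additionally shifts the
#' mean by `tr(H Sigma) / 2` and adds `tr((H Sigma)^2) / 2` to the variance,
#' with `H` the parameter Hessian of the curve.  Produced for parity with the
#' standard uncertainty-propagation toolchain; the Monte-Carlo band is the
#' primary output.
#'
#' @inheritParams mc_confidence_band
#' @param order 1 or 2.
#' @return A `curve_band` tibble (x, fit, lo95, hi95) with a `method`
#'   attribute `"taylor1"` or `"taylor2"`.
#' @export
taylor_band <- function(fit, x_grid, order = 1, level = 0.95) {
  sigma <- fit$covariance
  a <- fit$coef
  b <- fit$exp
  z <- -stats::qnorm((1 - level) / 2)
  xe <- x_grid^b
  lxe <- log(x_grid)
  center <- power_curve(a, b, x_grid)
  vr <- numeric(length(x_grid))
  for (k in seq_along(x_grid)) {
    g <- c(xe[k], a * xe[k] * lxe[k])
    vr[k] <- drop(t(g) %*% sigma %*% g)
    if (order >= 2) {
      H <- matrix(c(
        0, xe[k] * lxe[k],
        xe[k] * lxe[k], a * xe[k] * lxe[k]^2
      ), 2, 2)
      hs <- H %*% sigma
      center[k] <- center[k] + 0.5 * sum(diag(hs))
      vr[k] <- vr[k] + 0.5 * sum(diag(hs %*% hs))
    }
  }
  band <- tibble::tibble(
    x = x_grid,
    fit = center,
    lo95 = center - z * sqrt(vr),
    hi95 = center + z * sqrt(vr)
  )
  structure(band, class = c("curve_band", class(band)),
    method = paste0("taylor", order)
  )
}

#' Duration at which the fitted curve reaches a target bias
#'
#' Solves `coef * x^exp - 1 = target_bias` analytically:
#' `x = ((1 + target) / coef)^(1 / exp)`.  Returns `NA` when the solution
#' falls outside `[x_min, x_max]` (the observed duration range, 6-200 min by
#' default) or when the curve cannot reach the target there (`exp <= 0` with
#' `coef < 1 + target`).
#'
#' @param fit A `power_fit`.
#' @param target_bias Target bias level (default 0, parity).
#' @param x_min,x_max Duration range searched.
#' @return The crossing duration, or `NA_real_` ("none").
#' @export
crossing_duration <- function(fit, target_bias = 0, x_min = 6, x_max = 200) {
  ratio <- (1 + target_bias) / fit$coef
  if (!is.finite(ratio) || ratio <= 0 || fit$exp == 0) {
    return(NA_real_)
  }
  x <- ratio^(1 / fit$exp)
  if (!is.finite(x) || x < x_min || x > x_max) {
    return(NA_real_)
  }
  x
}
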