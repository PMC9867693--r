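test_that("noiseless curves reproduce their generating parameters to 1e-6", {
  x <- 6:200
  for (truth in list(c(0.1729, 0.2853), c(0.3879, 0.1414), c(0.5, -0.2))) {
    y <- truth[1] * x^truth[2] - 1
    fit <- fit_power(x, y)
    expect_lt(abs(fit$coef - truth[1]), 1e-6)
    expect_lt(abs(fit$exp - truth[2]), 1e-6)
    expect_lt(fit$residual_se, 1e-8)
    expect_true(fit$converged)
  }
})

test_that("constant bias data collapse to an exponent of zero", {
  x <- c(6, 12, 30, 60, 120, 200)
  fit <- fit_power(x, rep(-0.5, 6))
  expect_equal(fit$coef * mean(x)^fit$exp, 0.5, tolerance = 1e-6)
  expect_lt(abs(fit$exp), 1e-6)
  expect_lt(fit$residual_se, 1e-8)
})

test_that("the optimum matches a grid-search oracle on small noisy datasets", {
  set.seed(55)
  for (rep in 1:3) {
    x <- sort(runif(18, 6, 200))
    y <- 0.25 * x^0.22 - 1 + rnorm(18, 0, 0.1)
    fit <- fit_power(x, y)
    oracle <- oracle_power_fit(x, y)
    expect_lt(abs(fit$coef - oracle[1]), 5e-4)
    expect_lt(abs(fit$exp - oracle[2]), 5e-4)
    # first-order optimality at the returned optimum
    expect_lt(fit$gradient_norm, 1e-5 * (1 + sum(abs(y))))
  }
})

test_that("inference columns are internally consistent", {
  set.seed(66)
  x <- runif(100, 6, 200)
  y <- 0.2 * x^0.25 - 1 + rnorm(100, 0, 0.2)
  fit <- fit_power(x, y)
  expect_equal(fit$t_coef, fit$coef / fit$se_coef)
  expect_equal(fit$t_exp, fit$exp / fit$se_exp)
  expect_equal(fit$dof, 98L)
  expect_equal(fit$p_exp, 2 * pt(-abs(fit$t_exp), 98), tolerance = 1e-12)
  expect_equal(fit$covariance, t(fit$covariance))
  td <- tidy(fit)
  expect_equal(td$estimate, c(fit$coef, fit$exp))
  gl <- glance(fit)
  expect_equal(gl$sigma, fit$residual_se)

  # agreement with an independent Levenberg-Marquardt implementation
  skip_if_not_installed("minpack.lm")
  nls_fit <- minpack.lm::nlsLM(
    y ~ a * x^b - 1,
    start = list(a = 0.2, b = 0.3),
    control = minpack.lm::nls.lm.control(ftol = 1e-12, ptol = 1e-12)
  )
  expect_equal(unname(coef(nls_fit)), c(fit$coef, fit$exp), tolerance = 1e-6)
  expect_equal(summary(nls_fit)$sigma, fit$residual_se, tolerance = 1e-6)
})

test_that("fit_power validates its inputs", {
  expect_error(fit_power(c(1, 2), c(1, 2)), "at least 3")
  expect_error(fit_power(c(-1, 2, 3), c(0, 0, 0)), "positive")
  expect_error(predict_bias(power_fit(0.2, 0.3), -5), "positive")
})

test_that("predictions reproduce published worked examples", {
  ref <- reference_power_fits()
  fits <- purrr::map(seq_len(4), function(i) power_fit(ref$coef[i], ref$exp[i]))
  expect_equal(round(predict_bias(fits[[1]], 60), 2), -0.44)
  expect_equal(round(predict_bias(fits[[2]], 60), 2), -0.31)
  expect_equal(round(completeness_percent(fits[[1]], 60)), 56)
  expect_equal(round(completeness_percent(fits[[4]], 60)), 59)
  # bias 0 means 100% completeness
  flat <- power_fit(1, 0)
  expect_equal(completeness_percent(flat, 60), 100)
  # x -> 0+ with positive exponent drives bias to -1
  expect_equal(predict_bias(fits[[1]], 1e-12), -1, tolerance = 1e-3)
  # and richness gain is monotone: positive coef and exponent
  curve <- predict_bias(fits[[1]], seq(6, 200, by = 1))
  expect_true(all(diff(curve) > 0))
})

test_that("crossing duration solves the curve analytically within the range", {
  expect_equal(crossing_duration(power_fit(0.5, 0.5), 0, x_min = 1), 4)
  # published observed-vs-observed curve: parity lies beyond 200 min
  ref1 <- power_fit(0.1729, 0.2853)
  expect_true(is.na(crossing_duration(ref1, 0)))
  analytic <- (1 / 0.1729)^(1 / 0.2853)
  expect_equal(crossing_duration(ref1, 0, x_max = 1000), analytic)
  expect_gt(analytic, 200)
  # a flat or decaying curve below parity never reaches it
  expect_true(is.na(crossing_duration(power_fit(0.8, 0), 0)))
  expect_true(is.na(crossing_duration(power_fit(0.8, -0.3), 0)))
})

test_that("monte-carlo bands are seeded, centred and monotone in covariance", {
  x <- 6:200
  y <- 0.17 * x^0.29 - 1 + withr::with_seed(9, rnorm(length(x), 0, 0.25))
  fit <- fit_power(x, y)
  grid <- c(6, 30, 60, 120, 200)
  b1 <- mc_confidence_band(fit, grid, n_sims = 4000, seed = 3)
  b2 <- mc_confidence_band(fit, grid, n_sims = 4000, seed = 3)
  expect_identical(b1$lo95, b2$lo95) # determinism

  expect_true(all(b1$lo95 <= b1$fit + 1e-9))
  expect_true(all(b1$hi95 >= b1$fit - 1e-9))

  # zero covariance: band collapses to the fitted curve
  degenerate <- fit
  degenerate$covariance <- matrix(0, 2, 2)
  b0 <- mc_confidence_band(degenerate, grid, n_sims = 500, seed = 1)
  expect_equal(b0$lo95, b0$fit, tolerance = 1e-12)
  expect_equal(b0$hi95, b0$fit, tolerance = 1e-12)

  # wider covariance gives pointwise wider bands
  wide <- fit
  wide$covariance <- fit$covariance * 9
  bw <- mc_confidence_band(wide, grid, n_sims = 4000, seed = 3)
  expect_true(all(bw$hi95 - bw$lo95 >= b1$hi95 - b1$lo95 - 1e-9))

  # non-positive-definite covariance is repaired with a warning
  broken <- fit
  broken$covariance <- matrix(c(1e-4, 2e-4, 2e-4, 1e-4), 2, 2)
  expect_warning(mc_confidence_band(broken, grid, n_sims = 200, seed = 1), "clipping")
})

test_that("taylor bands agree with the monte-carlo band to first order", {
  # small parameter uncertainty keeps the curve in its linearization regime,
  # where all three propagation methods must coincide
  x <- rep(6:200, 3)
  y <- 0.17 * x^0.29 - 1 + withr::with_seed(10, rnorm(length(x), 0, 0.08))
  fit <- fit_power(x, y)
  grid <- c(10, 60, 150)
  mc <- mc_confidence_band(fit, grid, n_sims = 20000, seed = 4)
  t1 <- taylor_band(fit, grid, order = 1)
  t2 <- taylor_band(fit, grid, order = 2)
  width <- function(b) b$hi95 - b$lo95
  expect_equal(width(t1), width(mc), tolerance = 0.1)
  expect_equal(width(t2), width(mc), tolerance = 0.1)
  expect_equal(attr(t2, "method"), "taylor2")
})
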