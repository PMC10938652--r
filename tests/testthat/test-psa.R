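test_that("exponential MLE has its closed form and variance", {
  d <- event_data(c(2, 3, 5, 7, 1), c(1, 1, 0, 1, 1))
  f <- fit_mle("exponential", d)
  expect_equal(f$params[["rate"]], 4 / 18, tolerance = 1e-12)
  expect_equal(f$vcov[1, 1], 1 / 4, tolerance = 1e-12)
  expect_equal(f$loglik, 4 * log(4 / 18) - (4 / 18) * 18, tolerance = 1e-12)
  expect_error(fit_mle("exponential", event_data(c(1, 2), c(1, 0))),
               class = "survpoint_optimisation_error")
})

test_that("two-parameter MLEs recover simulation truth and match an independent fitter", {
  d <- simulate_event_data("weibull", c(shape = 1.5, scale = 2), 500,
                           seed = 12)
  f <- fit_mle("weibull", d)
  se <- sqrt(diag(f$vcov))
  expect_lt(abs(log(f$params[["shape"]]) - log(1.5)), 3 * se[1])
  expect_lt(abs(log(f$params[["scale"]]) - log(2)), 3 * se[2])
  expect_true(isSymmetric(f$vcov) && all(eigen(f$vcov)$values > 0))
  skip_if_not_installed("flexsurv")
  ref <- flexsurv::flexsurvreg(survival::Surv(time, status) ~ 1, data = d,
                               dist = "weibull")
  # flexsurv parameterises the same way; compare natural-scale estimates
  expect_equal(unname(f$params),
               unname(ref$res[c("shape", "scale"), "est"]), tolerance = 1e-4)
  expect_equal(f$loglik, ref$loglik, tolerance = 1e-6)
  expect_equal(unname(f$vcov), unname(ref$cov), tolerance = 1e-2)
})

test_that("censored gompertz likelihoods are fitted on the identity/log scale", {
  d <- simulate_event_data("gompertz", c(shape = 0.15, rate = 0.08), 400,
                           cutoff = 15, seed = 21)
  f <- fit_mle("gompertz", d)
  se <- sqrt(diag(f$vcov))
  expect_lt(abs(f$params[["shape"]] - 0.15), 3 * se[1])
  expect_lt(abs(log(f$params[["rate"]]) - log(0.08)), 3 * se[2])
})

test_that("parameter sampling is centred, in-domain and reproducible", {
  centre <- c(shape = log(1.5), scale = log(2))
  zero <- matrix(0, 2, 2)
  draws <- sample_parameters("weibull", centre, zero, 50, seed = 1)
  expect_true(all(draws[, "shape"] == 1.5 & draws[, "scale"] == 2))
  tiny <- diag(1e-12, 2)
  draws2 <- sample_parameters("weibull", centre, tiny, 50, seed = 1)
  expect_lt(max(abs(t(draws2) - c(1.5, 2))), 1e-5)
  expect_true(all(draws2 > 0))
  # CLT: transformed-scale sample mean within 4 SE of the centre
  vc <- matrix(c(0.04, 0.01, 0.01, 0.09), 2)
  big <- sample_parameters("weibull", centre, vc, 10000, seed = 2)
  means <- colMeans(log(big))
  expect_lt(abs(means[1] - centre[1]), 4 * sqrt(0.04 / 10000))
  expect_lt(abs(means[2] - centre[2]), 4 * sqrt(0.09 / 10000))
  # bitwise reproducibility per seed
  expect_identical(sample_parameters("gompertz", c(0.1, log(0.2)),
                                     diag(0.01, 2), 20, seed = 9),
                   sample_parameters("gompertz", c(0.1, log(0.2)),
                                     diag(0.01, 2), 20, seed = 9))
  expect_error(sample_parameters("weibull", centre, diag(1, 3), 10),
               class = "survpoint_argument_error")
})

test_that("PSA bands collapse with zero variance and start at 1", {
  sol <- solve_points("exponential", surv_points(2, 0.5))
  fit <- fit_mle("exponential",
                 simulate_event_data("exponential", c(rate = 0.35), 100,
                                     seed = 5))
  fit$vcov[] <- 0
  b <- psa_bands(sol$model, fit, grid = seq(0, 10, 0.5), n = 100, seed = 3)
  expect_equal(b$lower, b$point, tolerance = 1e-14)
  expect_equal(b$upper, b$point, tolerance = 1e-14)
  expect_equal(b$lower[1], 1)
  expect_equal(b$upper[1], 1)
})

test_that("PSA bands match closed-form quantiles for a log-normal rate", {
  # with var(log rate) = v, S_draw(t) = exp(-rate * t) has quantiles
  # exp(-q_rate * t) where q_rate are the lognormal quantiles of the rate
  sol <- solve_points("exponential", surv_points(2, 0.5))
  rate <- sol$model$params[["rate"]]
  fit <- fit_mle("exponential",
                 simulate_event_data("exponential", c(rate = 0.35), 100,
                                     seed = 5))
  fit$vcov[] <- 0.04
  grid <- c(0, 1, 2, 5, 10)
  b <- psa_bands(sol$model, fit, grid, n = 1000, seed = 8)
  lo_expect <- exp(-exp(log(rate) + qnorm(0.975) * 0.2) * grid)
  hi_expect <- exp(-exp(log(rate) - qnorm(0.975) * 0.2) * grid)
  expect_equal(b$lower, lo_expect, tolerance = 0.02)
  expect_equal(b$upper, hi_expect, tolerance = 0.02)
  # bands bracket the point estimate and are monotone curves
  expect_true(all(b$lower <= b$point & b$point <= b$upper))
  expect_true(all(diff(b$lower) <= 1e-12) && all(diff(b$upper) <= 1e-12))
  # bitwise reproducibility per seed
  b2 <- psa_bands(sol$model, fit, grid, n = 1000, seed = 8)
  expect_identical(b$lower, b2$lower)
  expect_identical(b$draws, b2$draws)
})

test_that("bootstrap KM PSA is reproducible and isolates its sources", {
  d <- simulate_event_data("weibull", c(shape = 1.3, scale = 10), 120,
                           seed = 14)
  fit <- fit_mle("gompertz", d)
  pts <- surv_points(c(15, 40), c(0.25, 0.08))
  grid <- seq(0, 40, 2)
  b1 <- bootstrap_km_psa(d, "gompertz", pts, 6, fit, grid, n = 5, seed = 4)
  b2 <- bootstrap_km_psa(d, "gompertz", pts, 6, fit, grid, n = 5, seed = 4)
  expect_identical(b1$lower, b2$lower)
  expect_s3_class(b1, "psa_result")
  # zero vcov: band width before t0 comes from KM resampling alone,
  # and the curves all pass through their own re-anchored points
  fit0 <- fit
  fit0$vcov[] <- 0
  b3 <- bootstrap_km_psa(d, "gompertz", pts, 6, fit0, grid, n = 40,
                         seed = 11)
  pre <- grid > 0 & grid < 6
  expect_true(any(b3$upper[pre] - b3$lower[pre] > 0))
  expect_equal(b3$point[1], 1)
  # a 1-event dataset yields skipped replicates, reported not fatal
  d_small <- event_data(c(1, 2, 3, 4), c(0, 0, 0, 1))
  fit_exp <- fit_mle("exponential", simulate_event_data("exponential",
                                                        c(rate = 0.3), 50,
                                                        seed = 2))
  b4 <- suppressWarnings(
    bootstrap_km_psa(d_small, "exponential", surv_points(10, 0.2), 0.5,
                     fit_exp, seq(0, 10, 1), n = 30, seed = 6))
  expect_gt(b4$n_skipped, 0)
})
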