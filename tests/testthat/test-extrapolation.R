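test_that("piecewise models convert points to the conditional scale and join continuously", {
  pw <- build_piecewise("gompertz", surv_points(c(17, 60), c(0.25, 0.10)),
                        t0 = 7.7, anchor = 0.5, time_unit = "months")
  # conditional conversion: divide by the anchor, shift by t0
  expect_equal(pw$tail_solution$points$time, c(9.3, 52.3))
  expect_equal(pw$tail_solution$points$survival, c(0.5, 0.2))
  # the assembled unconditional curve passes through the specified points
  expect_equal(surv_prob(pw, 17), 0.25, tolerance = 1e-9)
  expect_equal(surv_prob(pw, 60), 0.10, tolerance = 1e-9)
  # continuity at the join
  eps <- 1e-9
  expect_equal(surv_prob(pw, 7.7), 0.5)
  expect_lt(abs(surv_prob(pw, 7.7 - eps) - surv_prob(pw, 7.7 + eps)), 1e-8)
  # degenerate prefix: t0 = 0 with anchor 1 is a plain solved model
  pts <- surv_points(c(2, 5), c(0.7, 0.3))
  pw0 <- build_piecewise("weibull", pts, t0 = 0, anchor = 1)
  plain <- solve_points("weibull", pts)$model
  t <- seq(0, 10, 0.25)
  expect_equal(surv_prob(pw0, t), surv_prob(plain, t), tolerance = 1e-12)
  # ordering / monotonicity violations
  expect_error(build_piecewise("weibull", surv_points(5, 0.6), t0 = 7.7,
                               anchor = 0.5),
               class = "survpoint_ordering_error")
  expect_error(build_piecewise("weibull", surv_points(10, 0.6), t0 = 7.7,
                               anchor = 0.5),
               class = "survpoint_monotonicity_error")
})

test_that("piecewise models take their anchor from a KM prefix", {
  d <- event_data(c(1, 2, 3, 4), c(1, 1, 1, 1))
  km <- kaplan_meier(d)
  pw <- build_piecewise("exponential", surv_points(10, 0.2), t0 = 2, km = km)
  expect_equal(pw$anchor, 0.5)
  expect_equal(surv_prob(pw, 1.5), 0.75)      # KM step before t0
  expect_equal(surv_prob(pw, 10), 0.2, tolerance = 1e-10)
  # continuity invariant across random joins with a cure tail
  pw2 <- build_piecewise("weibull", surv_points(c(10, 30), c(0.3, 0.12)),
                         t0 = 2, km = km, pi = 0.1)
  expect_s3_class(pw2$tail, "cure_model")
  expect_equal(surv_prob(pw2, 2), 0.5, tolerance = 1e-10)
  expect_equal(surv_prob(pw2, c(10, 30)), c(0.3, 0.12), tolerance = 1e-8)
})

test_that("background mortality substitutes the population hazard as a floor", {
  lt <- flat_life_table(0.02)
  # inner hazard always above the floor: no change
  inner <- surv_model("exponential", c(rate = 0.1), "years")
  adj <- apply_background_mortality(inner, lt, 40, "female", "years",
                                    horizon = 30)
  t <- seq(0, 30, 0.5)
  expect_equal(surv_prob(adj, t), surv_prob(inner, t), tolerance = 1e-6)
  # inner hazard always below: population survival results
  inner2 <- surv_model("exponential", c(rate = 0.001), "years")
  adj2 <- apply_background_mortality(inner2, lt, 40, "female", "years",
                                     horizon = 30)
  expect_equal(surv_prob(adj2, t), exp(-0.02 * t), tolerance = 1e-5)
  # plateau-type gompertz: hazard decays to zero, so the floor takes over
  g <- surv_model("gompertz", c(shape = -0.5, rate = 0.3), "years")
  adj3 <- apply_background_mortality(g, lt, 40, "male", "years",
                                     horizon = 40)
  tt <- seq(0.5, 40, 0.5)
  # equality region only up to quadrature tolerance of the hazard integral
  expect_true(all(surv_prob(adj3, tt) <= surv_prob(g, tt) + 1e-6))
  expect_lt(surv_prob(adj3, 40), surv_prob(g, 40))
  expect_true(all(surv_hazard(adj3, tt) >= 0.02 - 1e-12))
  # fine-grid numerical oracle for the max-hazard integral
  oracle_H <- integrate(function(u) pmax(surv_hazard(g, pmax(u, 1e-12)), 0.02),
                        0, 25, rel.tol = 1e-10, subdivisions = 2000)$value
  expect_equal(surv_prob(adj3, 25), exp(-oracle_H), tolerance = 1e-5)
  # horizon beyond the life table's coverage names the last covered age
  expect_error(apply_background_mortality(inner, lt, 100, "female", "years",
                                          horizon = 30),
               class = "survpoint_coverage_error")
})

test_that("model averages are pointwise means bounded by their members", {
  m1 <- surv_model("exponential", c(rate = 1))
  m3 <- surv_model("exponential", c(rate = 3))
  expect_equal(average_models(list(m1, m3), 1), (exp(-1) + exp(-3)) / 2)
  expect_equal(average_models(list(m1, m3), 0), 1)
  expect_equal(average_models(list(m1), 2), exp(-2))
  avg <- model_average(list(m1, m3))
  t <- seq(0, 5, 0.1)
  s <- surv_prob(avg, t)
  expect_true(all(s <= surv_prob(m1, t) & s >= surv_prob(m3, t)))
  expect_error(model_average(list()), class = "survpoint_argument_error")
  # identical members reproduce the member
  expect_equal(surv_prob(model_average(list(m1, m1)), t), surv_prob(m1, t))
})

test_that("RMST matches closed forms and is linear and monotone", {
  expect_equal(rmst(surv_model("exponential", c(rate = 1)), 5)$value,
               1 - exp(-5), tolerance = 1e-6)
  expect_equal(rmst(surv_model("exponential", c(rate = 0.5)), 40)$value, 2,
               tolerance = 1e-4)
  cm <- cure_model(0.4, surv_model("exponential", c(rate = 1)))
  expect_equal(rmst(cm, 10)$value, 0.4 * 10 + 0.6 * (1 - exp(-10)),
               tolerance = 1e-5)
  # refining the grid moves the value by < 1e-6 relative
  v1 <- rmst(cm, 10)$value
  v2 <- rmst(cm, 10, n_grid = 40001)$value
  expect_lt(abs(v1 - v2) / v2, 1e-6)
  # RMST of an average equals the average of RMSTs
  m1 <- surv_model("weibull", c(shape = 1.4, scale = 3))
  m2 <- surv_model("loglogistic", c(shape = 2, scale = 2.5))
  expect_equal(rmst(model_average(list(m1, m2)), 8)$value,
               (rmst(m1, 8)$value + rmst(m2, 8)$value) / 2,
               tolerance = 1e-9)
  # monotone non-decreasing in tau
  taus <- c(1, 2, 5, 10, 20)
  vals <- vapply(taus, function(x) rmst(m1, x)$value, numeric(1))
  expect_true(all(diff(vals) > 0))
  expect_true(all(vals <= taus))
})

test_that("hazard curves expose the floor and the family shapes", {
  grid <- seq(0.5, 20, 0.5)
  hc <- hazard_curve(surv_model("exponential", c(rate = 0.3)), grid)
  expect_equal(hc$hazard, rep(0.3, length(grid)))
  hc2 <- hazard_curve(surv_model("gompertz", c(shape = 0.1, rate = 0.05)),
                      grid)
  expect_true(all(diff(hc2$hazard) > 0))
  # composite models: central-difference hazard agrees with the closed form
  pw <- build_piecewise("gompertz", surv_points(c(17, 60), c(0.25, 0.10)),
                        t0 = 7.7, anchor = 0.5, time_unit = "months")
  tail_h <- surv_hazard(pw$tail, 12 - 7.7)
  fd <- (log(surv_prob(pw, 12 - 1e-6)) -
         log(surv_prob(pw, 12 + 1e-6))) / 2e-6
  expect_equal(surv_hazard(pw, 12), tail_h, tolerance = 1e-10)
  expect_equal(tail_h, fd, tolerance = 1e-5)
  # mortality-adjusted hazard never falls below the population hazard
  lt <- flat_life_table(0.02)
  adj <- apply_background_mortality(surv_model("gompertz",
                                               c(shape = -0.5, rate = 0.3),
                                               "years"),
                                    lt, 40, "female", "years", horizon = 30)
  hc3 <- hazard_curve(adj, seq(0.5, 30, 0.5))
  expect_true(all(hc3$hazard >= 0.02 - 1e-12))
})
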