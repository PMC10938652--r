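# Shared generators for property-style tests. Parameter ranges cover the
# shapes relevant to survival extrapolation, including plateau-type
# (negative-shape) Gompertz models.

rand_params <- function(family) {
  switch(family,
    exponential = c(rate = exp(runif(1, -2, 1))),
    weibull     = c(shape = exp(runif(1, -1, 1)), scale = exp(runif(1, -1, 2))),
    loglogistic = c(shape = exp(runif(1, -1, 1)), scale = exp(runif(1, -1, 2))),
    lognormal   = c(meanlog = runif(1, -1, 2), sdlog = exp(runif(1, -1, 0.7))),
    gompertz    = c(shape = runif(1, -0.3, 0.5), rate = exp(runif(1, -2, 0)))
  )
}

# strictly decreasing two-point coordinate set
rand_pair <- function() {
  t1 <- exp(runif(1, -1, 1))
  t2 <- t1 * exp(runif(1, 0.2, 1.5))
  s1 <- runif(1, 0.4, 0.95)
  s2 <- runif(1, 0.01, 0.8 * s1)
  surv_points(c(t1, t2), c(s1, s2))
}

# feasible survival probabilities for quantile round trips (above any
# gompertz plateau)
rand_feasible_p <- function(model, n = 5) {
  lo <- 0.001
  if (model$family == "gompertz" && model$params[["shape"]] < 0) {
    lo <- max(lo, exp(model$params[["rate"]] / model$params[["shape"]]) + 0.01)
  }
  if (lo >= 0.98) lo <- 0.9
  runif(n, lo, 0.99)
}

# Independent oracle for two-parameter solves: a generic damped Newton on
# the simultaneous survival equations g(S(t_i; theta)) = g(s_i), with
# numeric Jacobian and step halving. Knows nothing about the closed-form
# linearisations; uses only surv_prob.
generic_root_solve <- function(fam, pts, g) {
  trans <- function(theta) {
    if (fam == "lognormal") c(theta[1], exp(theta[2])) else exp(theta)
  }
  fn <- function(theta) {
    m <- surv_model(fam, trans(theta))
    g(surv_prob(m, pts$time)) - g(pts$survival)
  }
  # neutral start: unit shape at the data's time scale
  theta <- if (fam == "lognormal") c(mean(log(pts$time)), 0)
           else c(0, log(pts$time[1]))
  for (it in 1:200) {
    f0 <- fn(theta)
    n0 <- sum(f0^2)
    if (sqrt(n0) < 1e-12) break
    J <- matrix(0, 2, 2)
    h <- 1e-7 * pmax(abs(theta), 1)
    for (j in 1:2) {
      tp <- theta
      tp[j] <- tp[j] + h[j]
      J[, j] <- (fn(tp) - f0) / h[j]
    }
    step <- tryCatch(solve(J, -f0), error = function(e) -f0)
    lam <- 1
    repeat {
      cand <- theta + lam * step
      f1 <- tryCatch(fn(cand), error = function(e) rep(Inf, 2))
      if (all(is.finite(f1)) && sum(f1^2) < n0) break
      lam <- lam / 2
      if (lam < 1e-12) {
        cand <- theta
        break
      }
    }
    if (identical(cand, theta)) break
    theta <- cand
  }
  trans(theta)
}

write_event_csv <- function(time, status, ...) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  utils::write.csv(data.frame(time = time, status = status, ...), path,
                   row.names = FALSE)
  path
}

flat_life_table <- function(hazard = 0.02, ages = 0:110) {
  life_table(data.frame(age = rep(ages, 2),
                        sex = rep(c("female", "male"), each = length(ages)),
                        qx = 1 - exp(-hazard)))
}
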