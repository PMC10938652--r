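# Probabilistic sensitivity analysis. Maximum-likelihood fits to uploaded
# event data supply a variance-covariance matrix on a transformed scale
# (log for strictly positive parameters, identity for the gompertz shape
# and lognormal meanlog). That matrix is re-centred on the interpolated
# parameters and sampled from a multivariate normal, so the uncertainty in
# the data acts as a proxy for the uncertainty of the extrapolation.

# transformed <-> natural scale maps, in family parameter order
sp_transform <- function(family, params) {
  info <- .sp_family_info(family)
  out <- as.numeric(params)
  out[info$log_scale] <- log(out[info$log_scale])
  setNames(out, info$par_names)
}

sp_back_transform <- function(family, theta) {
  info <- .sp_family_info(family)
  out <- as.numeric(theta)
  out[info$log_scale] <- exp(out[info$log_scale])
  setNames(out, info$par_names)
}

# right-censored log-likelihood: sum_events log h(t_i) + sum_all log S(t_i)
sp_loglik <- function(family, params, data, time_unit) {
  m <- surv_model(family, params, time_unit)
  sum(data$status * log(surv_hazard(m, data$time))) -
    sum(surv_cumhaz(m, data$time))
}

#' Maximum-likelihood fit of a parametric family to event data
#'
#' Fits by quasi-Newton optimisation of the right-censored log-likelihood
#' on the transformed scale (the exponential has the closed form
#' `rate = events / total follow-up`, with `var(log rate) = 1/events`).
#' The variance-covariance matrix is the inverse of the numerically
#' evaluated observed information. The fit is estimated solely from the
#' data and is independent of any interpolated coordinates.
#'
#' @param family Family name.
#' @param data An [event_data()] object with at least 2 events.
#' @return An object of class `mle_fit`: list with `family`, `params`
#'   (natural scale), `estimate_t` (transformed scale), `vcov`
#'   (transformed scale), `loglik`, `converged`.
#' @export
fit_mle <- function(family, data) {
  stopifnot(inherits(data, "event_data"))
  info <- .sp_family_info(family)
  time_unit <- attr(data, "time_unit")
  d <- sum(data$status)
  if (d < 2) {
    sp_stop("at least 2 events are required for a stable fit",
            "survpoint_optimisation_error")
  }
  if (family == "exponential") {
    total <- sum(data$time)
    rate <- d / total
    fit <- list(
      family = family, params = c(rate = rate),
      estimate_t = c(rate = log(rate)),
      vcov = matrix(1 / d, 1, 1, dimnames = list("rate", "rate")),
      loglik = d * log(rate) - rate * total,
      converged = TRUE, time_unit = time_unit)
    return(structure(fit, class = "mle_fit"))
  }
  start <- switch(family,
    weibull     = c(shape = 1, scale = sum(data$time) / d),
    loglogistic = c(shape = 1, scale = sum(data$time) / d),
    lognormal   = c(meanlog = mean(log(data$time)),
                    sdlog = max(sd(log(data$time)), 0.25)),
    gompertz    = c(shape = 0.001, rate = d / sum(data$time))
  )
  nll <- function(theta) {
    p <- sp_back_transform(family, theta)
    ll <- tryCatch(sp_loglik(family, p, data, time_unit),
                   error = function(e) -Inf)
    if (!is.finite(ll)) 1e10 else -ll
  }
  opt <- optim(sp_transform(family, start), nll, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-14), hessian = TRUE)
  if (opt$convergence != 0) {
    sp_stop(sprintf("likelihood optimisation did not converge (code %d): %s",
                    opt$convergence, paste(opt$message, collapse = " ")),
            "survpoint_optimisation_error")
  }
  vcov <- tryCatch(solve(opt$hessian), error = function(e) NULL)
  if (is.null(vcov) || any(!is.finite(vcov)) || any(diag(vcov) <= 0)) {
    sp_stop("observed information is singular; no covariance available",
            "survpoint_covariance_error")
  }
  vcov <- (vcov + t(vcov)) / 2
  dimnames(vcov) <- list(info$par_names, info$par_names)
  est_t <- setNames(opt$par, info$par_names)
  structure(list(family = family,
                 params = sp_back_transform(family, est_t),
                 estimate_t = est_t, vcov = vcov, loglik = -opt$value,
                 converged = TRUE, time_unit = time_unit),
            class = "mle_fit")
}

#' @export
print.mle_fit <- function(x, ...) {
  cat(sprintf("MLE fit: %s, log-likelihood %.4f\n", x$family, x$loglik))
  print(signif(x$params, 6))
  cat("vcov (transformed scale):\n")
  print(signif(x$vcov, 4))
  invisible(x)
}

#' Sample parameter vectors around a transformed-scale centre
#'
#' Multivariate normal draws on the transformed scale (log for strictly
#' positive parameters), back-transformed to the natural scale — the
#' draws therefore always satisfy the family's positivity constraints.
#'
#' @param family Family name (fixes the transformation).
#' @param center_t Transformed-scale centre (e.g. the interpolated
#'   parameters passed through the log map).
#' @param vcov Transformed-scale variance-covariance matrix.
#' @param n Number of draws.
#' @param seed Optional integer seed for reproducibility.
#' @return An `n` by `n_params` matrix of natural-scale parameter vectors.
#' @export
sample_parameters <- function(family, center_t, vcov, n, seed = NULL) {
  info <- .sp_family_info(family)
  if (length(center_t) != info$n_params ||
      !all(dim(vcov) == info$n_params)) {
    sp_stop("centre / vcov dimension does not match the family",
            "survpoint_argument_error")
  }
  if (!is.null(seed)) set.seed(seed)
  draws <- MASS::mvrnorm(n, mu = as.numeric(center_t), Sigma = vcov)
  draws <- matrix(draws, ncol = info$n_params)
  nat <- draws
  nat[, info$log_scale] <- exp(nat[, info$log_scale, drop = FALSE])
  colnames(nat) <- info$par_names
  nat
}

.sp_parametric_core <- function(model) {
  if (inherits(model, "surv_model")) return(model)
  if (inherits(model, "cure_model")) return(model$base)
  if (inherits(model, "piecewise_model")) return(.sp_parametric_core(model$tail))
  sp_stop("model has no single parametric core for PSA",
          "survpoint_argument_error")
}

.sp_with_core_params <- function(model, params) {
  if (inherits(model, "surv_model")) {
    return(surv_model(model$family, params, model$time_unit))
  }
  if (inherits(model, "cure_model")) {
    return(cure_model(model$pi, .sp_with_core_params(model$base, params)))
  }
  if (inherits(model, "piecewise_model")) {
    out <- model
    out$tail <- .sp_with_core_params(model$tail, params)
    return(out)
  }
  sp_stop("cannot substitute parameters into this model type",
          "survpoint_argument_error")
}

sp_percentile_bands <- function(curves) {
  list(lower = apply(curves, 2, quantile, probs = 0.025, names = FALSE),
       upper = apply(curves, 2, quantile, probs = 0.975, names = FALSE))
}

#' Probabilistic sensitivity analysis bands around an interpolated model
#'
#' Draws parameter vectors from a multivariate normal with the fitted
#' variance-covariance (see [fit_mle()]) re-centred on the model's
#' interpolated parameters, evaluates the survival curve for each draw on
#' the time grid, and reports the pointwise 2.5th and 97.5th percentiles.
#'
#' @param model A `surv_model`, `cure_model` or `piecewise_model` whose
#'   parametric core belongs to `fit$family`.
#' @param fit An [fit_mle()] result of the same family.
#' @param grid Time grid for the bands.
#' @param n Number of draws (default 1000).
#' @param seed Optional integer seed.
#' @return An object of class `psa_result`: list with `grid`, `point`
#'   (point-estimate curve), `lower`, `upper`, `draws` (parameter matrix),
#'   `n`, `seed`.
#' @export
psa_bands <- function(model, fit, grid, n = 1000, seed = NULL) {
  stopifnot(inherits(fit, "mle_fit"))
  core <- .sp_parametric_core(model)
  if (core$family != fit$family) {
    sp_stop(sprintf("fit family '%s' does not match model family '%s'",
                    fit$family, core$family), "survpoint_argument_error")
  }
  grid <- .sp_check_t(grid)
  center_t <- sp_transform(core$family, core$params)
  draws <- sample_parameters(core$family, center_t, fit$vcov, n, seed)
  m <- vapply(seq_len(n), function(i) {
    surv_prob(.sp_with_core_params(model, draws[i, ]), grid)
  }, numeric(length(grid)))
  curves <- if (is.null(dim(m))) matrix(m, ncol = 1) else t(m)
  bands <- sp_percentile_bands(curves)
  structure(list(grid = grid, point = surv_prob(model, grid),
                 lower = bands$lower, upper = bands$upper,
                 draws = draws, n = n, seed = seed, n_skipped = 0L),
            class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("PSA result: %d draws on a grid of %d times", x$n,
              length(x$grid)))
  if (x$n_skipped > 0) cat(sprintf(" (%d replicates skipped)", x$n_skipped))
  cat("\n")
  invisible(x)
}

#' Export PSA bands as a data frame
#'
#' @param x A `psa_result`.
#' @param ... Unused.
#' @return Data frame with columns `time`, `point`, `lower`, `upper`,
#'   suitable for writing to CSV for economic-model ingestion.
#' @export
as.data.frame.psa_result <- function(x, ...) {
  data.frame(time = x$grid, point = x$point, lower = x$lower,
             upper = x$upper)
}

#' Bootstrap-plus-parametric PSA for a piecewise model
#'
#' Combines the two sources of uncertainty in a KM + parametric-tail
#' extrapolation: each iteration resamples the event records with
#' replacement, rebuilds the Kaplan-Meier prefix and its anchor at `t0`,
#' re-solves the tail through the re-anchored conditional points, and then
#' draws the tail parameters from the fitted variance-covariance re-centred
#' on that iteration's solution. Percentile bands are taken over the
#' assembled curves. Replicates whose resample has no events, no support at
#' `t0`, or an anchor at or below a specified point survival are skipped
#' and counted.
#'
#' @param data [event_data()] to resample.
#' @param family Tail family.
#' @param points [surv_points()] on the unconditional scale.
#' @param t0 Join time.
#' @param fit [fit_mle()] result for the tail family.
#' @param grid Time grid for the bands.
#' @param n Number of bootstrap iterations.
#' @param seed Optional integer seed.
#' @param pi Optional tail cure fraction.
#' @return A `psa_result` with `n_skipped` reporting discarded replicates.
#' @export
bootstrap_km_psa <- function(data, family, points, t0, fit, grid,
                             n = 1000, seed = NULL, pi = NULL) {
  stopifnot(inherits(data, "event_data"), inherits(fit, "mle_fit"))
  grid <- .sp_check_t(grid)
  if (!is.null(seed)) set.seed(seed)
  point_est <- build_piecewise(family, points, t0, km = kaplan_meier(data),
                               pi = pi)
  curves <- matrix(NA_real_, nrow = n, ncol = length(grid))
  n_skipped <- 0L
  for (i in seq_len(n)) {
    idx <- sample.int(nrow(data), replace = TRUE)
    boot <- event_data(data$time[idx], data$status[idx],
                       attr(data, "time_unit"))
    pw <- tryCatch({
      km <- kaplan_meier(boot)
      build_piecewise(family, points, t0, km = km, pi = pi)
    }, survpoint_error = function(e) NULL)
    if (is.null(pw)) {
      n_skipped <- n_skipped + 1L
      next
    }
    core <- .sp_parametric_core(pw)
    draw <- MASS::mvrnorm(1, mu = sp_transform(core$family, core$params),
                          Sigma = fit$vcov)
    p <- sp_back_transform(core$family, draw)
    curves[i, ] <- tryCatch(
      surv_prob(.sp_with_core_params(pw, p), pmin(grid, Inf)),
      survpoint_error = function(e) rep(NA_real_, length(grid)))
    if (anyNA(curves[i, ])) n_skipped <- n_skipped + 1L
  }
  keep <- stats::complete.cases(curves)
  if (!any(keep)) {
    sp_stop("every bootstrap replicate was skipped", "survpoint_argument_error")
  }
  bands <- sp_percentile_bands(curves[keep, , drop = FALSE])
  structure(list(grid = grid, point = surv_prob(point_est, grid),
                 lower = bands$lower, upper = bands$upper,
                 draws = NULL, n = n, seed = seed, n_skipped = n_skipped),
            class = "psa_result")
}
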