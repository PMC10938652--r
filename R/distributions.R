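# Closed-form survival, hazard, cumulative-hazard and quantile functions for
# the five supported families, in the parameterisation used by standard
# survival-modelling software:
#   exponential  S(t) = exp(-rate * t)
#   weibull      S(t) = exp(-(t/scale)^shape)
#   loglogistic  S(t) = 1 / (1 + (t/scale)^shape)
#   lognormal    S(t) = 1 - Phi((log t - meanlog)/sdlog)
#   gompertz     S(t) = exp(-(rate/shape) * (exp(shape*t) - 1)),
#                reducing to exponential at shape = 0; shape < 0 gives a
#                survival plateau at exp(rate/shape).

.sp_families <- list(
  exponential = list(n_params = 1L, par_names = "rate",
                     positive = "rate", log_scale = TRUE),
  weibull     = list(n_params = 2L, par_names = c("shape", "scale"),
                     positive = c("shape", "scale"), log_scale = c(TRUE, TRUE)),
  loglogistic = list(n_params = 2L, par_names = c("shape", "scale"),
                     positive = c("shape", "scale"), log_scale = c(TRUE, TRUE)),
  lognormal   = list(n_params = 2L, par_names = c("meanlog", "sdlog"),
                     positive = "sdlog", log_scale = c(FALSE, TRUE)),
  gompertz    = list(n_params = 2L, par_names = c("shape", "rate"),
                     positive = "rate", log_scale = c(FALSE, TRUE))
)

#' Supported parametric families
#'
#' @return Character vector of family names. The exponential has one
#'   parameter; all other families have two.
#' @export
sp_families <- function() names(.sp_families)

#' Number of parameters of a family
#'
#' @param family Family name (see [sp_families()]).
#' @return Integer: 1 for the exponential, 2 otherwise.
#' @export
n_params <- function(family) {
  .sp_family_info(family)$n_params
}

.sp_family_info <- function(family) {
  if (!is.character(family) || length(family) != 1 ||
      is.na(match(family, names(.sp_families)))) {
    sp_stop(sprintf("unknown family '%s'; supported: %s",
                    paste(family, collapse = ","),
                    paste(names(.sp_families), collapse = ", ")),
            "survpoint_domain_error")
  }
  .sp_families[[family]]
}

#' Construct a parametric survival model
#'
#' @param family One of `"exponential"`, `"weibull"`, `"loglogistic"`,
#'   `"lognormal"`, `"gompertz"`.
#' @param params Named numeric vector of parameters. Names and constraints:
#'   exponential `rate > 0`; weibull and loglogistic `shape > 0`,
#'   `scale > 0`; lognormal `meanlog` (any real), `sdlog > 0`; gompertz
#'   `shape` (any real, negative values give a survival plateau),
#'   `rate > 0`.
#' @param time_unit Time unit of `t` in all evaluations: `"days"`,
#'   `"weeks"`, `"months"` or `"years"`.
#' @return An object of class `surv_model`.
#' @examples
#' m <- surv_model("weibull", c(shape = 1.5, scale = 2), "years")
#' surv_prob(m, c(0, 1, 5))
#' @export
surv_model <- function(family, params, time_unit = "months") {
  info <- .sp_family_info(family)
  sp_check_time_unit(time_unit)
  params <- unlist(params)
  if (length(params) != info$n_params ||
      (!is.null(names(params)) && !setequal(names(params), info$par_names))) {
    sp_stop(sprintf("family '%s' needs parameters (%s)", family,
                    paste(info$par_names, collapse = ", ")),
            "survpoint_domain_error")
  }
  if (is.null(names(params))) names(params) <- info$par_names
  params <- params[info$par_names]
  if (any(!is.finite(params))) {
    sp_stop("parameters must be finite", "survpoint_domain_error")
  }
  bad <- info$positive[params[info$positive] <= 0]
  if (length(bad)) {
    sp_stop(sprintf("parameter(s) %s must be strictly positive",
                    paste(bad, collapse = ", ")),
            "survpoint_domain_error")
  }
  structure(list(family = family, params = params, time_unit = time_unit),
            class = "surv_model")
}

#' @export
print.surv_model <- function(x, ...) {
  cat(sprintf("Parametric survival model: %s (time in %s)\n",
              x$family, x$time_unit))
  print(signif(x$params, 6))
  invisible(x)
}

#' Mixture cure model
#'
#' Overall survival `S(t) = pi + (1 - pi) * S_base(t)`: a fraction `pi` of
#' the population is never at risk of the event, so the curve plateaus at
#' `pi` instead of falling to zero.
#'
#' @param pi Cure fraction in `[0, 1)`.
#' @param base A [surv_model()] for the uncured subpopulation.
#' @return An object of class `cure_model`.
#' @export
cure_model <- function(pi, base) {
  if (!is.numeric(pi) || length(pi) != 1 || is.na(pi) || pi < 0 || pi >= 1) {
    sp_stop("cure fraction pi must lie in [0, 1)", "survpoint_domain_error")
  }
  stopifnot(inherits(base, "surv_model"))
  structure(list(pi = pi, base = base, time_unit = base$time_unit),
            class = "cure_model")
}

#' @export
print.cure_model <- function(x, ...) {
  cat(sprintf("Mixture cure model: pi = %g over %s base\n", x$pi,
              x$base$family))
  print(signif(x$base$params, 6))
  invisible(x)
}

#' Survival probability
#'
#' Evaluates `S(t)` for any model object in the package (parametric, cure,
#' piecewise, mortality-adjusted, model average). `S(0) = 1` and the curve
#' is non-increasing for every valid model.
#'
#' @param x A model object.
#' @param t Vector of non-negative times in the model's time unit.
#' @param ... Unused.
#' @return Vector of survival probabilities in `[0, 1]`.
#' @export
surv_prob <- function(x, t, ...) UseMethod("surv_prob")

#' Hazard rate
#'
#' Instantaneous event rate `h(t) = -d log S(t) / dt`. For composite models
#' without a closed form the hazard is computed by central differences of
#' `-log S`. At `t = 0` the mathematical limit is returned where it exists
#' (`0` for Weibull/log-logistic with `shape > 1` and for the log-normal;
#' `Inf` for `shape < 1`).
#'
#' @inheritParams surv_prob
#' @return Vector of non-negative hazard rates (events per time unit).
#' @export
surv_hazard <- function(x, t, ...) UseMethod("surv_hazard")

#' Cumulative hazard
#'
#' `H(t) = -log S(t)`, with `H(0) = 0`.
#'
#' @inheritParams surv_prob
#' @export
surv_cumhaz <- function(x, t, ...) UseMethod("surv_cumhaz")

#' Survival quantile (inverse survival function)
#'
#' Returns the time `t` at which `S(t) = p`. For a Gompertz model with
#' negative shape the survival function plateaus at `exp(rate/shape)`;
#' probabilities at or below the plateau are infeasible and raise an error
#' of class `survpoint_infeasible_quantile`.
#'
#' @param x A model object.
#' @param p Survival probability in `(0, 1)`.
#' @param ... Unused.
#' @export
surv_quantile <- function(x, p, ...) UseMethod("surv_quantile")

.sp_check_t <- function(t, allow_zero = TRUE) {
  if (!is.numeric(t) || any(is.na(t)) ||
      any(t < 0) || (!allow_zero && any(t == 0))) {
    sp_stop(if (allow_zero) "t must be non-negative" else "t must be positive",
            "survpoint_domain_error")
  }
  as.numeric(t)
}

# Gompertz cumulative hazard with the shape -> 0 removable singularity
# patched by its series limit (H ~ rate * t when |shape * t| is tiny).
gompertz_cumhaz <- function(shape, rate, t) {
  small <- abs(shape * t) < 1e-10
  h <- numeric(length(t))
  h[small] <- rate * t[small]
  if (any(!small)) {
    h[!small] <- rate * expm1(shape * t[!small]) / shape
  }
  h
}

#' @export
surv_cumhaz.surv_model <- function(x, t, ...) {
  t <- .sp_check_t(t)
  p <- x$params
  switch(x$family,
    exponential = p[["rate"]] * t,
    weibull     = (t / p[["scale"]])^p[["shape"]],
    loglogistic = log1p((t / p[["scale"]])^p[["shape"]]),
    lognormal   = ifelse(t == 0, 0,
                    -pnorm(log(t), p[["meanlog"]], p[["sdlog"]],
                           lower.tail = FALSE, log.p = TRUE)),
    gompertz    = gompertz_cumhaz(p[["shape"]], p[["rate"]], t)
  )
}

#' @export
surv_prob.surv_model <- function(x, t, ...) {
  exp(-surv_cumhaz(x, t))
}

#' @export
surv_hazard.surv_model <- function(x, t, ...) {
  t <- .sp_check_t(t)
  p <- x$params
  switch(x$family,
    exponential = rep(p[["rate"]], length(t)),
    weibull     = {
      k <- p[["shape"]]; s <- p[["scale"]]
      ifelse(t == 0,
             if (k > 1) 0 else if (k == 1) 1 / s else Inf,
             (k / s) * (t / s)^(k - 1))
    },
    loglogistic = {
      k <- p[["shape"]]; s <- p[["scale"]]
      ifelse(t == 0,
             if (k > 1) 0 else if (k == 1) 1 / s else Inf,
             (k / s) * (t / s)^(k - 1) / (1 + (t / s)^k))
    },
    lognormal   = {
      ifelse(t == 0, 0,
             dlnorm(t, p[["meanlog"]], p[["sdlog"]]) /
               pnorm(log(t), p[["meanlog"]], p[["sdlog"]], lower.tail = FALSE))
    },
    gompertz    = p[["rate"]] * exp(p[["shape"]] * t)
  )
}

#' @export
surv_quantile.surv_model <- function(x, p, ...) {
  if (!is.numeric(p) || any(is.na(p)) || any(p <= 0) || any(p >= 1)) {
    sp_stop("p must lie strictly in (0, 1)", "survpoint_domain_error")
  }
  par <- x$params
  H <- -log(p)  # target cumulative hazard
  switch(x$family,
    exponential = H / par[["rate"]],
    weibull     = par[["scale"]] * H^(1 / par[["shape"]]),
    loglogistic = par[["scale"]] * (expm1(H))^(1 / par[["shape"]]),
    lognormal   = exp(par[["meanlog"]] + par[["sdlog"]] * qnorm(1 - p)),
    gompertz    = {
      b <- par[["shape"]]; a <- par[["rate"]]
      if (abs(b) < 1e-14) {
        H / a
      } else {
        arg <- 1 + b * H / a
        if (any(arg <= 0)) {
          sp_stop(sprintf(
            "survival plateau exp(rate/shape) = %.6g exceeds requested p; quantile infeasible",
            exp(a / b)), "survpoint_infeasible_quantile")
        }
        log(arg) / b
      }
    }
  )
}

#' Cure-model survival (convenience wrapper)
#'
#' @param cure A [cure_model()].
#' @param t Non-negative times.
#' @return `pi + (1 - pi) * S_base(t)`.
#' @export
cure_survival <- function(cure, t) surv_prob(cure, t)

#' @export
surv_prob.cure_model <- function(x, t, ...) {
  x$pi + (1 - x$pi) * surv_prob(x$base, t)
}

#' @export
surv_cumhaz.cure_model <- function(x, t, ...) {
  -log(surv_prob(x, t))
}

#' @export
surv_hazard.cure_model <- function(x, t, ...) {
  t <- .sp_check_t(t)
  sb <- surv_prob(x$base, t)
  (1 - x$pi) * surv_hazard(x$base, t) * sb / (x$pi + (1 - x$pi) * sb)
}

#' @export
surv_quantile.cure_model <- function(x, p, ...) {
  if (any(p <= x$pi)) {
    sp_stop(sprintf("survival plateaus at the cure fraction %g; p must exceed it",
                    x$pi), "survpoint_infeasible_quantile")
  }
  surv_quantile(x$base, (p - x$pi) / (1 - x$pi))
}

# Default hazard for composite models: central difference of -log S with a
# relative step, h(t) = (log S(t-d) - log S(t+d)) / (2 d), d = 1e-5 * t.
#' @export
surv_hazard.default <- function(x, t, ...) {
  t <- .sp_check_t(t, allow_zero = FALSE)
  d <- 1e-5 * t
  (log(surv_prob(x, t - d)) - log(surv_prob(x, t + d))) / (2 * d)
}

# Default quantile for composite models: bracketed root of S(t) - p.
#' @export
surv_quantile.default <- function(x, p, ...) {
  if (!is.numeric(p) || length(p) != 1 || is.na(p) || p <= 0 || p >= 1) {
    sp_stop("p must lie strictly in (0, 1)", "survpoint_domain_error")
  }
  f <- function(t) surv_prob(x, t) - p
  hi <- 1
  for (i in 1:200) {
    if (f(hi) <= 0) break
    hi <- hi * 2
  }
  if (f(hi) > 0) {
    sp_stop("survival never falls to the requested probability within the searchable horizon",
            "survpoint_infeasible_quantile")
  }
  uniroot(f, c(0, hi), tol = 1e-12)$root
}
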