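# Synthetic fixtures: right-censored trial data drawn from known models by
# inverse-transform sampling, a Gompertz-Makeham life table, and the worked
# coordinate sets used throughout the package examples.

#' Simulate right-censored event data from a known model
#'
#' Event times are drawn by inverse-transform sampling through the family's
#' quantile function (`t = S^{-1}(u)`, `u ~ Uniform(0,1)`); the observed
#' time is the minimum of the event time, an optional independent
#' exponential censoring time and an administrative cutoff. For a Gompertz
#' model with negative shape a fraction `exp(rate/shape)` of subjects never
#' experience the event; those subjects are censored at the cutoff, which
#' must then be finite.
#'
#' @param family Family name.
#' @param params Named parameter vector (see [surv_model()]).
#' @param n Number of subjects.
#' @param cutoff Administrative censoring time (default `Inf`).
#' @param censor_rate Rate of independent exponential censoring
#'   (default 0 = none).
#' @param seed Optional integer seed; identical seeds give identical data.
#' @param time_unit Time unit of the simulated times.
#' @return An [event_data()] object.
#' @export
simulate_event_data <- function(family, params, n, cutoff = Inf,
                                censor_rate = 0, seed = NULL,
                                time_unit = "months") {
  if (!is.numeric(n) || n < 1) {
    sp_stop("n must be at least 1", "survpoint_domain_error")
  }
  model <- surv_model(family, params, time_unit)
  plateau <- 0
  if (family == "gompertz" && model$params[["shape"]] < 0) {
    plateau <- exp(model$params[["rate"]] / model$params[["shape"]])
    if (plateau > 0 && !is.finite(cutoff)) {
      sp_stop(sprintf(
        "gompertz survival plateaus at %.4g: a finite cutoff is required to censor the immortal fraction",
        plateau), "survpoint_domain_error")
    }
  }
  if (!is.null(seed)) set.seed(seed)
  u <- runif(n)
  t_event <- rep(Inf, n)
  feasible <- u > plateau
  if (any(feasible)) {
    t_event[feasible] <- surv_quantile(model, u[feasible])
  }
  t_cens <- if (censor_rate > 0) rexp(n, censor_rate) else rep(Inf, n)
  t_cens <- pmin(t_cens, cutoff)
  obs <- pmin(t_event, t_cens)
  if (any(!is.finite(obs))) {
    sp_stop("simulation produced infinite observation times; supply a finite cutoff or censor_rate",
            "survpoint_domain_error")
  }
  event_data(pmax(obs, .Machine$double.xmin),
             as.numeric(t_event <= t_cens), time_unit)
}

#' Synthetic Gompertz-Makeham life table
#'
#' Annual death probabilities `qx = 1 - exp(-(A + B * c^age))` for ages
#' `0..100` and both sexes, with the male hazard scaled by
#' `male_factor`. Defaults give a plausible adult mortality schedule
#' (annual hazard about 5e-4 at age 30 rising to about 0.02 at age 70 for
#' females). Hazards implying `qx >= 0.999` are capped with a warning.
#'
#' @param ages Integer ages covered (default `0:100`).
#' @param A Makeham age-independent hazard component (`>= 0`).
#' @param B Gompertz baseline (`> 0`).
#' @param c Gompertz rate of ageing (`> 1`).
#' @param male_factor Multiplier on the male hazard.
#' @return A [life_table()].
#' @export
synthetic_life_table <- function(ages = 0:100, A = 2e-4, B = 2.7e-5,
                                 c = 1.1, male_factor = 1.4) {
  if (A < 0 || B <= 0 || c <= 1) {
    sp_stop("require A >= 0, B > 0, c > 1", "survpoint_domain_error")
  }
  h_f <- A + B * c^ages
  h_m <- male_factor * h_f
  cap <- -log1p(-0.999)
  if (any(c(h_f, h_m) > cap)) {
    sp_warn("hazards capped so that qx <= 0.999", "survpoint_capped_qx")
    h_f <- pmin(h_f, cap); h_m <- pmin(h_m, cap)
  }
  life_table(data.frame(
    age = rep(ages, 2),
    sex = rep(c("female", "male"), each = length(ages)),
    qx = 1 - exp(-c(h_f, h_m))))
}

#' Worked-example coordinate sets
#'
#' The coordinate sets used in the package's worked examples:
#' \describe{
#'   \item{pessimistic}{Expert-opinion pair `S(1.46) = 0.691`,
#'     `S(4.73) = 0.101` (years) — a pessimistic long-term scenario.}
#'   \item{optimistic}{The shared early coordinate with the optimistic
#'     late coordinate `S(12.7) = 0.108` (years).}
#'   \item{piecewise}{A piecewise scenario in months: join at the observed
#'     median `t0 = 7.7` with anchor `S(t0) = 0.5`, interpolating a later
#'     follow-up point `(17, 0.25)` and an external registry 5-year
#'     survival estimate `(60, 0.10)`, with a Gompertz tail.}
#' }
#' Also included is `km_data`, a simulated right-censored dataset
#' (synthetic, not digitised from any trial) rescaled so its Kaplan-Meier
#' median is exactly 7.7 months, for overlay and bootstrap demonstrations.
#'
#' @return Named list with elements `pessimistic`, `optimistic`,
#'   `piecewise` and `km_data`.
#' @export
example_coordinate_sets <- function() {
  km_data <- simulate_event_data("exponential", c(rate = log(2) / 7.7),
                                 n = 200, cutoff = 40, seed = 771,
                                 time_unit = "months")
  km <- kaplan_meier(km_data)
  med <- km$time[min(which(km$surv <= 0.5))]
  km_data$time <- km_data$time * 7.7 / med
  list(
    pessimistic = surv_points(c(1.46, 4.73), c(0.691, 0.101)),
    optimistic = surv_points(c(1.46, 12.7), c(0.691, 0.108)),
    piecewise = list(t0 = 7.7, anchor = 0.5, family = "gompertz",
                     points = surv_points(c(17, 60), c(0.25, 0.10)),
                     time_unit = "months"),
    km_data = km_data
  )
}
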