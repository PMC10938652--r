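# Assembly of solved models into deliverable extrapolations: piecewise
# KM + parametric-tail joins, background-mortality hazard floors, model
# averages, hazard curves and restricted mean survival time.

#' Piecewise model: Kaplan-Meier prefix with a conditional parametric tail
#'
#' Up to the join time `t0` the curve follows the Kaplan-Meier estimate (or,
#' without data, a straight line from `(0, 1)` to the anchor). From `t0`
#' onward it follows `anchor * S_tail(t - t0)`, where the tail is a
#' parametric (optionally cure) model solved through the user's coordinates
#' converted to the conditional scale: a point `(t_i, s_i)` specified on
#' the *unconditional* survival scale becomes `(t_i - t0, s_i / anchor)`.
#' The assembled curve is continuous at `t0` and passes through every
#' specified unconditional coordinate.
#'
#' @param family Tail family name.
#' @param points [surv_points()] on the unconditional survival scale; all
#'   times must exceed `t0` and all survivals must be below the anchor.
#' @param t0 Join time (`>= 0`).
#' @param anchor Survival at `t0`, in `(0, 1]`. Defaults to the KM step
#'   value at `t0` when `km` is supplied.
#' @param km Optional [kaplan_meier()] curve used as the prefix.
#' @param pi Optional cure fraction for the tail (on the conditional
#'   scale); `NULL` or `0` for a plain tail.
#' @param time_unit Time unit (taken from `km` when supplied).
#' @return An object of class `piecewise_model`.
#' @examples
#' pw <- build_piecewise("gompertz", surv_points(c(17, 60), c(0.25, 0.10)),
#'                       t0 = 7.7, anchor = 0.5, time_unit = "months")
#' surv_prob(pw, c(7.7, 17, 60))
#' @export
build_piecewise <- function(family, points, t0, anchor = NULL, km = NULL,
                            pi = NULL, time_unit = "months") {
  if (!is.numeric(t0) || length(t0) != 1 || is.na(t0) || t0 < 0) {
    sp_stop("t0 must be a non-negative time", "survpoint_domain_error")
  }
  if (!is.null(km)) {
    stopifnot(inherits(km, "km_curve"))
    time_unit <- km$time_unit
    if (is.null(anchor)) anchor <- km_survival_at(km, t0)
  }
  if (is.null(anchor)) {
    sp_stop("supply either a KM curve or an explicit anchor S(t0)",
            "survpoint_domain_error")
  }
  if (!is.numeric(anchor) || length(anchor) != 1 || is.na(anchor) ||
      anchor <= 0 || anchor > 1) {
    sp_stop("anchor must lie in (0, 1]", "survpoint_domain_error")
  }
  if (t0 == 0 && anchor != 1) {
    sp_stop("anchor must be 1 when t0 = 0", "survpoint_domain_error")
  }
  pts <- as.data.frame(points)
  if (any(pts$time <= t0)) {
    sp_stop("all interpolation points must lie strictly after t0",
            "survpoint_ordering_error")
  }
  if (any(pts$survival >= anchor)) {
    sp_stop("all point survivals must lie strictly below the anchor S(t0)",
            "survpoint_monotonicity_error")
  }
  cond <- surv_points(pts$time - t0, pts$survival / anchor)
  sol <- if (!is.null(pi) && pi > 0) {
    solve_cure(family, pi, cond, time_unit)
  } else {
    solve_points(family, cond, time_unit)
  }
  structure(list(t0 = t0, anchor = anchor, km = km, tail = sol$model,
                 tail_solution = sol, points = pts, time_unit = time_unit),
            class = "piecewise_model")
}

#' @export
print.piecewise_model <- function(x, ...) {
  cat(sprintf("Piecewise model: %s prefix to t0 = %g %s (anchor %g), then:\n",
              if (is.null(x$km)) "linear anchor" else "Kaplan-Meier",
              x$t0, x$time_unit, x$anchor))
  print(x$tail)
  invisible(x)
}

#' @export
surv_prob.piecewise_model <- function(x, t, ...) {
  t <- .sp_check_t(t)
  out <- numeric(length(t))
  pre <- t < x$t0
  if (any(pre)) {
    out[pre] <- if (!is.null(x$km)) {
      km_survival_at(x$km, t[pre])
    } else {
      1 + (x$anchor - 1) * t[pre] / x$t0
    }
  }
  if (any(!pre)) {
    out[!pre] <- x$anchor * surv_prob(x$tail, t[!pre] - x$t0)
  }
  out
}

#' @export
surv_cumhaz.piecewise_model <- function(x, t, ...) -log(surv_prob(x, t))

#' @export
surv_hazard.piecewise_model <- function(x, t, ...) {
  t <- .sp_check_t(t, allow_zero = FALSE)
  out <- numeric(length(t))
  tail_part <- t >= x$t0
  if (any(tail_part)) {
    out[tail_part] <- surv_hazard(x$tail, pmax(t[tail_part] - x$t0, 1e-12))
  }
  if (any(!tail_part)) {
    out[!tail_part] <- surv_hazard.default(x, t[!tail_part])
  }
  out
}

#' Evaluate any model's survival curve
#'
#' Uniform evaluation contract: dispatches to the model-specific
#' [surv_prob()] method.
#'
#' @param model Any model object (`surv_model`, `cure_model`,
#'   `piecewise_model`, `mortality_adjusted_model`, `model_average`).
#' @param t Non-negative times.
#' @export
evaluate <- function(model, t) surv_prob(model, t)

#' Apply a background general-population mortality floor
#'
#' Wherever the model's hazard falls below the age- and sex-matched
#' general-population hazard, the population hazard is used instead:
#' `h_adj(t) = max(h_model(t), h_pop(age0 + t / units_per_year, sex))`, and
#' the adjusted survival is `exp(-integral of h_adj)`. The population
#' hazard is piecewise constant per whole year of age (`-log(1 - qx)`,
#' divided by the number of time units per year). The adjustment is applied
#' after parameter estimation, so the curve may no longer pass through the
#' specified coordinates.
#'
#' The max-hazard is integrated by the midpoint rule on a uniform grid of
#' 20,000 intervals over `[0, horizon]`; evaluation interpolates the
#' resulting cumulative hazard.
#'
#' @param inner Any evaluable model.
#' @param table A [life_table()].
#' @param age0 Age in years at time 0.
#' @param sex `"female"` or `"male"`.
#' @param time_unit Time unit of the inner model.
#' @param horizon Evaluation horizon in time units; defaults to the time at
#'   which the life table runs out for this starting age. A horizon beyond
#'   the table's coverage raises an error naming the last covered age.
#' @return An object of class `mortality_adjusted_model`.
#' @export
apply_background_mortality <- function(inner, table, age0, sex,
                                       time_unit = "months",
                                       horizon = NULL) {
  stopifnot(inherits(table, "life_table"))
  sp_check_time_unit(time_unit)
  if (!sex %in% c("female", "male")) {
    sp_stop("sex must be 'female' or 'male'", "survpoint_domain_error")
  }
  conv <- .sp_time_units[[time_unit]]  # time units per year
  sub <- table[table$sex == sex, ]
  if (nrow(sub) == 0) {
    sp_stop(sprintf("life table has no rows for sex '%s'", sex),
            "survpoint_domain_error")
  }
  max_age <- max(sub$age)
  coverable <- (max_age + 1 - age0) * conv
  if (is.null(horizon)) horizon <- coverable
  if (horizon > coverable + 1e-9) {
    sp_stop(sprintf(
      "life table exhausted before the horizon: last covered age for sex '%s' is %d",
      sex, max_age), "survpoint_coverage_error")
  }
  n_int <- 20000L
  dt <- horizon / n_int
  mids <- (seq_len(n_int) - 0.5) * dt
  h_pop <- life_table_hazard(table, pmin(age0 + mids / conv, max_age), sex) / conv
  h_in <- surv_hazard(inner, mids)
  h_adj <- pmax(h_in, h_pop)
  H <- c(0, cumsum(h_adj * dt))
  structure(list(inner = inner, table = table, age0 = age0, sex = sex,
                 time_unit = time_unit, horizon = horizon, conv = conv,
                 grid = c(0, seq_len(n_int) * dt), cumhaz = H),
            class = "mortality_adjusted_model")
}

#' @export
print.mortality_adjusted_model <- function(x, ...) {
  cat(sprintf(
    "Mortality-adjusted model (age0 = %g, %s, horizon %g %s) wrapping:\n",
    x$age0, x$sex, x$horizon, x$time_unit))
  print(x$inner)
  invisible(x)
}

#' @export
surv_cumhaz.mortality_adjusted_model <- function(x, t, ...) {
  t <- .sp_check_t(t)
  if (any(t > x$horizon + 1e-9)) {
    sp_stop(sprintf("t beyond the mortality-adjustment horizon %g", x$horizon),
            "survpoint_coverage_error")
  }
  approx(x$grid, x$cumhaz, xout = pmin(t, x$horizon), rule = 2)$y
}

#' @export
surv_prob.mortality_adjusted_model <- function(x, t, ...) {
  exp(-surv_cumhaz(x, t))
}

#' @export
surv_hazard.mortality_adjusted_model <- function(x, t, ...) {
  t <- .sp_check_t(t, allow_zero = FALSE)
  h_pop <- life_table_hazard(
    x$table, pmin(x$age0 + t / x$conv, max(x$table$age[x$table$sex == x$sex])),
    x$sex) / x$conv
  pmax(surv_hazard(x$inner, t), h_pop)
}

#' Arithmetic mean of several survival models
#'
#' @param models Non-empty list of evaluable models.
#' @return An object of class `model_average` whose survival at `t` is the
#'   arithmetic mean of the members' survival at `t`.
#' @export
model_average <- function(models) {
  if (!is.list(models) || length(models) == 0) {
    sp_stop("models must be a non-empty list", "survpoint_argument_error")
  }
  structure(list(models = models,
                 time_unit = models[[1]]$time_unit),
            class = "model_average")
}

#' @export
surv_prob.model_average <- function(x, t, ...) {
  m <- vapply(x$models, function(mm) surv_prob(mm, t), numeric(length(t)))
  if (is.null(dim(m))) mean(m) else rowMeans(m)
}

#' @export
surv_cumhaz.model_average <- function(x, t, ...) -log(surv_prob(x, t))

#' Mean survival of a set of models at given times
#'
#' @param models Non-empty list of evaluable models.
#' @param t Non-negative times.
#' @export
average_models <- function(models, t) surv_prob(model_average(models), t)

#' Restricted mean survival time
#'
#' Area under the survival curve on `[0, tau]` by the trapezoidal rule on a
#' uniform grid: the expected survival time, truncated at the horizon, in
#' the model's time units (divide by time units per year for life-years).
#'
#' @param model Any evaluable model.
#' @param tau Positive horizon.
#' @param n_grid Number of grid points (default 10001).
#' @return An object of class `rmst_result`: list with `tau`, `value`,
#'   `n_grid`.
#' @export
rmst <- function(model, tau, n_grid = 10001) {
  if (!is.numeric(tau) || length(tau) != 1 || is.na(tau) || tau <= 0) {
    sp_stop("tau must be a positive horizon", "survpoint_domain_error")
  }
  grid <- seq(0, tau, length.out = n_grid)
  value <- trapz_uniform(surv_prob(model, grid), grid[2] - grid[1])
  structure(list(tau = tau, value = value, n_grid = n_grid),
            class = "rmst_result")
}

#' @export
print.rmst_result <- function(x, ...) {
  cat(sprintf("RMST over [0, %g]: %.6g time units (grid %d)\n",
              x$tau, x$value, x$n_grid))
  invisible(x)
}

#' Hazard rates along a time grid
#'
#' For parametric and cure models the closed-form hazard is used; for
#' composite models the hazard is computed as a central difference of
#' `-log S` with relative step `1e-5 * t`.
#'
#' @param model Any evaluable model.
#' @param grid Vector of positive times.
#' @return Data frame with columns `time` and `hazard`.
#' @export
hazard_curve <- function(model, grid) {
  grid <- .sp_check_t(grid, allow_zero = FALSE)
  data.frame(time = grid, hazard = surv_hazard(model, grid))
}
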