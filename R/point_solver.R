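# Exact interpolation of survival coordinates. Each family's survival
# function is rearranged so that an exactly-determined system (1 point for
# the exponential, 2 for the two-parameter families) has a unique solution:
#
#   exponential  rate = -log(s) / t
#   weibull      -log S = (t/scale)^shape is linear in log t on the
#                log(-log s) scale: shape is the slope, scale the intercept
#   loglogistic  same linearisation on log(1/s - 1)
#   lognormal    qnorm(1 - s) is linear in log t
#   gompertz     no closed form: the shape is the unique root of
#                (exp(b t2) - 1)/(exp(b t1) - 1) = log(s2)/log(s1),
#                a strictly increasing function of b with range (1, Inf),
#                solved by bracketed root finding; the rate then follows in
#                closed form.

#' Survival coordinates to interpolate
#'
#' @param time Vector of positive times.
#' @param survival Vector of survival probabilities strictly in `(0, 1)`.
#' @return A data frame of class `surv_points` with columns `time` and
#'   `survival`.
#' @examples
#' surv_points(c(1.46, 4.73), c(0.691, 0.101))
#' @export
surv_points <- function(time, survival) {
  if (length(time) != length(survival)) {
    sp_stop("time and survival must have equal length", "survpoint_domain_error")
  }
  structure(data.frame(time = as.numeric(time), survival = as.numeric(survival)),
            class = c("surv_points", "data.frame"))
}

#' Validate and order interpolation points
#'
#' Sorts the points by time and checks that there are exactly
#' `required_count` of them, that times are strictly increasing and
#' positive, and that survival probabilities are strictly decreasing and
#' inside `(0, 1)`.
#'
#' @param points A [surv_points()] object (or coercible data frame).
#' @param required_count Number of points the target family needs
#'   (1 for the exponential, 2 otherwise).
#' @return The points sorted by time.
#' @export
validate_points <- function(points, required_count) {
  if (is.null(points) || NROW(points) == 0) {
    sp_stop(sprintf("expected %d point(s), got 0", required_count),
            "survpoint_count_error")
  }
  points <- as.data.frame(points)
  if (!all(c("time", "survival") %in% names(points))) {
    sp_stop("points must have columns time and survival", "survpoint_domain_error")
  }
  if (NROW(points) != required_count) {
    sp_stop(sprintf("expected %d point(s), got %d", required_count, NROW(points)),
            "survpoint_count_error")
  }
  if (any(!is.finite(points$time)) || any(points$time <= 0)) {
    sp_stop("all times must be positive and finite", "survpoint_domain_error")
  }
  if (any(!is.finite(points$survival)) ||
      any(points$survival <= 0) || any(points$survival >= 1)) {
    sp_stop("all survival probabilities must lie strictly in (0, 1)",
            "survpoint_domain_error")
  }
  points <- points[order(points$time), , drop = FALSE]
  rownames(points) <- NULL
  if (required_count > 1) {
    if (any(diff(points$time) == 0)) {
      sp_stop("times must be distinct", "survpoint_tie_error")
    }
    if (any(diff(points$survival) >= 0)) {
      sp_stop("survival must be strictly decreasing in time",
              "survpoint_monotonicity_error")
    }
  }
  structure(points, class = c("surv_points", "data.frame"))
}

#' Gompertz shape from two survival coordinates
#'
#' Solves the shape equation
#' `(exp(b*t2) - 1) / (exp(b*t1) - 1) = log(s2) / log(s1)` for `b`. The
#' left-hand side, interpreted as `t2/t1` at `b = 0`, is continuous and
#' strictly increasing in `b` with range `(1, Inf)`, so the root is unique;
#' it is bracketed by doubling outward from `[-1, 1]` and refined by
#' bisection-based root finding.
#'
#' @param t1,s1 Earlier coordinate.
#' @param t2,s2 Later coordinate (`t2 > t1`, `s2 < s1`).
#' @return The shape `b` (negative values give a survival plateau).
#' @export
solve_gompertz_shape <- function(t1, s1, t2, s2) {
  R <- log(s2) / log(s1)  # > 1 for a strictly decreasing pair
  ratio <- function(b) {
    if (abs(b) < 1e-12) t2 / t1 else expm1(b * t2) / expm1(b * t1)
  }
  f <- function(b) log(ratio(b)) - log(R)
  lo <- -1; hi <- 1
  cap <- 500 / t2
  while (f(lo) > 0) {
    lo <- lo * 2
    if (-lo > cap) sp_stop("gompertz shape bracket expansion failed",
                           "survpoint_nonconvergence_error")
  }
  while (f(hi) < 0) {
    hi <- hi * 2
    if (hi > cap) sp_stop("gompertz shape bracket expansion failed",
                          "survpoint_nonconvergence_error")
  }
  b <- uniroot(f, c(lo, hi), tol = 1e-14, maxiter = 2000)$root
  if (abs(ratio(b) - R) > 1e-10 * max(1, R)) {
    sp_stop("gompertz shape root did not meet the ratio tolerance",
            "survpoint_nonconvergence_error")
  }
  b
}

.sp_solve_params <- function(family, points) {
  t <- points$time; s <- points$survival
  switch(family,
    exponential = c(rate = -log(s[1]) / t[1]),
    weibull = {
      y <- log(-log(s))
      k <- (y[2] - y[1]) / (log(t[2]) - log(t[1]))
      c(shape = k, scale = t[1] * (-log(s[1]))^(-1 / k))
    },
    loglogistic = {
      y <- log(1 / s - 1)
      k <- (y[2] - y[1]) / (log(t[2]) - log(t[1]))
      c(shape = k, scale = t[1] * exp(-y[1] / k))
    },
    lognormal = {
      z <- qnorm(1 - s)
      sdlog <- (log(t[2]) - log(t[1])) / (z[2] - z[1])
      c(meanlog = log(t[1]) - sdlog * z[1], sdlog = sdlog)
    },
    gompertz = {
      b <- solve_gompertz_shape(t[1], s[1], t[2], s[2])
      a <- if (abs(b) < 1e-12) {
        -log(s[1]) / t[1]
      } else {
        -log(s[1]) * b / expm1(b * t[1])
      }
      c(shape = b, rate = a)
    }
  )
}

.sp_solution <- function(model, points, method) {
  res <- abs(surv_prob(model, points$time) - points$survival)
  structure(list(model = model, points = points, residuals = res,
                 converged = max(res) < 1e-8, method = method),
            class = "point_solution")
}

#' @export
print.point_solution <- function(x, ...) {
  cat(sprintf("Point solution (%s, %s)\n",
              if (inherits(x$model, "cure_model")) x$model$base$family
              else x$model$family,
              x$method))
  print(x$model)
  cat(sprintf("max residual %.3g; converged: %s\n",
              max(x$residuals), x$converged))
  invisible(x)
}

#' Solve a family's parameters through specified coordinates
#'
#' Recovers the parameter vector for which the family's survival function
#' passes exactly through the supplied coordinates: one point for the
#' exponential, two for the two-parameter families. Closed forms are used
#' wherever one exists; the Gompertz shape requires a one-dimensional root
#' find (see [solve_gompertz_shape()]).
#'
#' @param family Family name.
#' @param points A [surv_points()] object with the family's required number
#'   of coordinates.
#' @param time_unit Time unit of the coordinates.
#' @return A `point_solution`: list with elements `model` (a
#'   [surv_model()]), `residuals` (per-point `|S(t_i) - s_i|`),
#'   `converged` (max residual below 1e-8) and `method`
#'   (`"closed_form"` or `"root_find"`).
#' @examples
#' solve_points("weibull", surv_points(c(1.46, 4.73), c(0.691, 0.101)), "years")
#' @export
solve_points <- function(family, points, time_unit = "months") {
  info <- .sp_family_info(family)
  points <- validate_points(points, info$n_params)
  params <- .sp_solve_params(family, points)
  if (any(!is.finite(params))) {
    sp_stop(sprintf("points are degenerate for family '%s' (non-finite solution)",
                    family), "survpoint_infeasible_error")
  }
  model <- surv_model(family, params, time_unit)
  .sp_solution(model, points,
               if (family == "gompertz") "root_find" else "closed_form")
}

#' Solve a mixture cure model through specified coordinates
#'
#' With cure fraction `pi` fixed, the overall coordinates `(t_i, s_i)` are
#' transformed to the uncured scale, `s_i' = (s_i - pi) / (1 - pi)`, and the
#' base family is solved through the transformed points, so the overall
#' curve `pi + (1 - pi) * S_base(t)` reproduces the originals.
#'
#' @param family Base family name.
#' @param pi Cure fraction in `[0, 1)`; every point survival must exceed it.
#' @inheritParams solve_points
#' @return A `point_solution` whose `model` is a [cure_model()]; residuals
#'   are on the overall survival scale.
#' @export
solve_cure <- function(family, pi, points, time_unit = "months") {
  info <- .sp_family_info(family)
  points <- validate_points(points, info$n_params)
  if (!is.numeric(pi) || length(pi) != 1 || is.na(pi) || pi < 0 || pi >= 1) {
    sp_stop("cure fraction pi must lie in [0, 1)", "survpoint_domain_error")
  }
  if (pi == 0) return(solve_points(family, points, time_unit))
  if (any(points$survival <= pi)) {
    sp_stop(sprintf(
      "point survival at or below the cure fraction %g cannot be reached: the curve plateaus at pi",
      pi), "survpoint_cure_infeasibility_error")
  }
  base_pts <- surv_points(points$time, (points$survival - pi) / (1 - pi))
  base <- solve_points(family, base_pts, time_unit)$model
  .sp_solution(cure_model(pi, base), points,
               if (family == "gompertz") "root_find" else "closed_form")
}

#' Solve every supported family through a shared set of coordinates
#'
#' Two-parameter families are solved through the two-point set; the
#' exponential is solved through its single point (by default the earlier
#' of the pair). Families that fail return the condition object describing
#' the failure instead of aborting the batch.
#'
#' @param points_two [surv_points()] with the two coordinates for the
#'   two-parameter families.
#' @param points_one Single coordinate for the exponential; defaults to the
#'   earliest of `points_two`.
#' @param time_unit Time unit of the coordinates.
#' @param pi Optional cure fraction applied to every family via
#'   [solve_cure()]; `0` (default) solves plain models.
#' @return Named list, one entry per family: a `point_solution` on success,
#'   a condition object on failure.
#' @export
solve_all <- function(points_two, points_one = NULL, time_unit = "months",
                      pi = 0) {
  if (is.null(points_one) && !is.null(points_two) && NROW(points_two) >= 1) {
    pts <- as.data.frame(points_two)
    first <- which.min(pts$time)
    points_one <- surv_points(pts$time[first], pts$survival[first])
  }
  out <- lapply(names(.sp_families), function(fam) {
    pts <- if (fam == "exponential") points_one else points_two
    tryCatch(
      if (pi > 0) solve_cure(fam, pi, pts, time_unit)
      else solve_points(fam, pts, time_unit),
      survpoint_error = function(e) e
    )
  })
  names(out) <- names(.sp_families)
  out
}
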