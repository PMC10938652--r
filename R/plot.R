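# Thin plotting layer: survival and hazard panels with optional KM overlay,
# in the base-graphics style of the field's survival packages.

#' Plot survival curves of one or more models
#'
#' @param models Named list of evaluable models.
#' @param horizon Right edge of the time axis.
#' @param km Optional [kaplan_meier()] curve to overlay as a step function.
#' @param points Optional [surv_points()] to mark.
#' @param n_grid Grid resolution.
#' @param ... Passed to [graphics::matplot()].
#' @return Invisibly, the data frame of plotted curves.
#' @export
plot_survival <- function(models, horizon, km = NULL, points = NULL,
                          n_grid = 401, ...) {
  grid <- seq(0, horizon, length.out = n_grid)
  curves <- sapply(models, surv_prob, t = grid)
  graphics::matplot(grid, curves, type = "l", lty = 1, ylim = c(0, 1),
                    xlab = sprintf("time (%s)", models[[1]]$time_unit),
                    ylab = "survival probability", ...)
  if (!is.null(km)) {
    graphics::lines(stats::stepfun(km$time, c(1, km$surv)), do.points = FALSE,
                    col = "grey40")
  }
  if (!is.null(points)) {
    graphics::points(points$time, points$survival, pch = 19)
  }
  if (!is.null(names(models))) {
    graphics::legend("topright", legend = names(models), col = seq_along(models),
                     lty = 1, bty = "n")
  }
  invisible(data.frame(time = grid, curves))
}

#' Plot hazard curves of one or more models
#'
#' @inheritParams plot_survival
#' @export
plot_hazard <- function(models, horizon, n_grid = 401, ...) {
  grid <- seq(horizon / n_grid, horizon, length.out = n_grid)
  curves <- sapply(models, function(m) hazard_curve(m, grid)$hazard)
  graphics::matplot(grid, curves, type = "l", lty = 1,
                    xlab = sprintf("time (%s)", models[[1]]$time_unit),
                    ylab = "hazard rate", ...)
  if (!is.null(names(models))) {
    graphics::legend("topleft", legend = names(models), col = seq_along(models),
                     lty = 1, bty = "n")
  }
  invisible(data.frame(time = grid, curves))
}
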