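# Right-censored event data, the Kaplan-Meier estimator (via
# survival::survfit, with Greenwood variance and log cumulative-hazard
# confidence intervals) and life tables of annual death probabilities.

#' Construct right-censored event data
#'
#' @param time Vector of positive observation times.
#' @param status Event indicator per record: 1 = event, 0 = censored.
#' @param time_unit Time unit of the observations.
#' @return An object of class `event_data` (a data frame with columns
#'   `time` and `status`).
#' @export
event_data <- function(time, status, time_unit = "months") {
  sp_check_time_unit(time_unit)
  time <- as.numeric(time); status <- as.numeric(status)
  if (length(time) != length(status)) {
    sp_stop("time and status must have equal length", "survpoint_domain_error")
  }
  if (any(!is.finite(time)) || any(time <= 0)) {
    sp_stop("all times must be positive and finite", "survpoint_domain_error")
  }
  if (!all(status %in% c(0, 1))) {
    sp_stop("status must be coded 0 (censored) / 1 (event)",
            "survpoint_coding_error")
  }
  structure(data.frame(time = time, status = status),
            class = c("event_data", "data.frame"), time_unit = time_unit)
}

#' Read right-censored event data from delimited text
#'
#' @param path Path to a CSV file.
#' @param time_col,status_col Column names holding the observation time and
#'   the event indicator.
#' @param status_map Optional named numeric vector translating status codes
#'   found in the file to 0/1, e.g. `c(event = 1, censored = 0)`. With the
#'   default `NULL` the column must already be coded 0/1.
#' @param time_unit Time unit of the observations.
#' @return An [event_data()] object. Rows with missing or non-positive
#'   times are dropped with a warning reporting the count.
#' @export
read_event_data <- function(path, time_col = "time", status_col = "status",
                            status_map = NULL, time_unit = "months") {
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(c(time_col, status_col), names(df))
  if (length(missing_cols)) {
    sp_stop(sprintf("column(s) %s not found in %s",
                    paste(missing_cols, collapse = ", "), path),
            "survpoint_schema_error")
  }
  time <- suppressWarnings(as.numeric(df[[time_col]]))
  status_raw <- df[[status_col]]
  if (!is.null(status_map)) {
    status <- unname(status_map[as.character(status_raw)])
  } else {
    status <- suppressWarnings(as.numeric(status_raw))
  }
  if (any(is.na(status)) || !all(status %in% c(0, 1))) {
    sp_stop("status column could not be parsed to 0/1 (supply status_map?)",
            "survpoint_coding_error")
  }
  bad <- is.na(time) | time <= 0
  if (any(bad)) {
    sp_warn(sprintf("%d row(s) with missing or non-positive time dropped",
                    sum(bad)), "survpoint_rows_dropped")
  }
  event_data(time[!bad], status[!bad], time_unit)
}

#' Kaplan-Meier product-limit estimate
#'
#' Computes the product-limit estimator with Greenwood variance of
#' `log S` and pointwise 95% confidence intervals on the log
#' cumulative-hazard scale (which keeps the interval inside `[0, 1]`).
#'
#' @param data An [event_data()] object with at least one event.
#' @return An object of class `km_curve` with elements `time`, `n_risk`,
#'   `n_event`, `surv`, `var_log_surv` (the Greenwood sum
#'   `sum d_i / (n_i (n_i - d_i))`), `lower`, `upper`, `max_time` (last
#'   follow-up) and the originating `data`.
#' @export
kaplan_meier <- function(data) {
  stopifnot(inherits(data, "event_data"))
  if (sum(data$status) == 0) {
    sp_stop("no events: the Kaplan-Meier curve is degenerate (constant 1)",
            "survpoint_degenerate_curve_error")
  }
  fit <- survival::survfit(survival::Surv(time, status) ~ 1,
                           data = data, conf.type = "log-log")
  structure(list(
    time = fit$time,
    n_risk = fit$n.risk,
    n_event = fit$n.event,
    surv = fit$surv,
    var_log_surv = fit$std.err^2,
    lower = fit$lower,
    upper = fit$upper,
    max_time = max(data$time),
    data = data,
    time_unit = attr(data, "time_unit")
  ), class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: %d records, %d events, follow-up to %g %s\n",
              nrow(x$data), sum(x$n_event), x$max_time, x$time_unit))
  invisible(x)
}

#' Kaplan-Meier survival at a time point
#'
#' Right-continuous step-function value of the product-limit estimate,
#' i.e. the value *after* any step occurring exactly at `t`.
#'
#' @param curve A [kaplan_meier()] curve.
#' @param t Time in `[0, last follow-up]`.
#' @export
km_survival_at <- function(curve, t) {
  stopifnot(inherits(curve, "km_curve"))
  t <- .sp_check_t(t)
  if (any(t > curve$max_time)) {
    sp_stop(sprintf("t beyond last observed follow-up time %g",
                    curve$max_time), "survpoint_out_of_support_error")
  }
  stats::stepfun(curve$time, c(1, curve$surv), right = FALSE)(t)
}

#' Read a life table of annual death probabilities
#'
#' Expects a long-format CSV with columns `age` (whole years), `sex`
#' (`"female"`/`"male"`) and `qx` (annual probability of death, in
#' `[0, 1)`). Ages must be contiguous within each sex. The annual hazard
#' `-log(1 - qx)` is precomputed.
#'
#' @param path Path to the CSV file.
#' @return An object of class `life_table`.
#' @export
read_life_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  life_table(df)
}

#' Construct a life table from a data frame
#'
#' @param df Data frame with columns `age`, `sex`, `qx`.
#' @return An object of class `life_table` (the data frame, validated, with
#'   an added `hazard` column `-log(1 - qx)` per year).
#' @export
life_table <- function(df) {
  missing_cols <- setdiff(c("age", "sex", "qx"), names(df))
  if (length(missing_cols)) {
    sp_stop(sprintf("life table must have columns age, sex, qx (missing: %s)",
                    paste(missing_cols, collapse = ", ")),
            "survpoint_schema_error")
  }
  if (any(!is.finite(df$qx)) || any(df$qx < 0) || any(df$qx >= 1)) {
    sp_stop("qx must lie in [0, 1)", "survpoint_domain_error")
  }
  if (!all(df$sex %in% c("female", "male"))) {
    sp_stop("sex must be 'female' or 'male'", "survpoint_domain_error")
  }
  for (sx in unique(df$sex)) {
    ages <- sort(df$age[df$sex == sx])
    if (length(ages) > 1 && any(diff(ages) != 1)) {
      sp_stop(sprintf("ages are not contiguous for sex '%s' (gap after age %d)",
                      sx, ages[which(diff(ages) != 1)[1]]),
              "survpoint_continuity_error")
    }
  }
  df$hazard <- -log1p(-df$qx)
  structure(df[order(df$sex, df$age), ],
            class = c("life_table", "data.frame"))
}

# Annual population hazard at (possibly fractional) ages, piecewise
# constant per whole year of age.
life_table_hazard <- function(table, age, sex) {
  sub <- table[table$sex == sex, ]
  if (nrow(sub) == 0) {
    sp_stop(sprintf("life table has no rows for sex '%s'", sex),
            "survpoint_domain_error")
  }
  idx <- match(floor(age), sub$age)
  if (any(is.na(idx))) {
    sp_stop(sprintf("life table exhausted: last covered age for sex '%s' is %d",
                    sex, max(sub$age)), "survpoint_coverage_error")
  }
  sub$hazard[idx]
}
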