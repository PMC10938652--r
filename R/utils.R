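# Classed conditions so callers can distinguish failure modes programmatically.
sp_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "survpoint_error")))
}

sp_warn <- function(msg, class = "survpoint_warning") {
  warning(warningCondition(msg, class = c(class, "survpoint_warning")))
}

# time units per year
.sp_time_units <- c(years = 1, months = 12, weeks = 52.18, days = 365.25)

sp_check_time_unit <- function(time_unit) {
  if (!is.character(time_unit) || length(time_unit) != 1 ||
      !time_unit %in% names(.sp_time_units)) {
    sp_stop(sprintf("time_unit must be one of: %s",
                    paste(names(.sp_time_units), collapse = ", ")),
            "survpoint_domain_error")
  }
  time_unit
}

trapz_uniform <- function(y, dx) {
  n <- length(y)
  dx * (sum(y) - (y[1] + y[n]) / 2)
}
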