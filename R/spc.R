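#' Shewhart individuals control charts
#'
#' Extreme values in a daily variable are defined against control limits
#' computed from the 35-day stable period: center = stable-period mean,
#' limits = center +/- 3 stable-period SDs (sample SD, n-1 denominator).
#' A day strictly outside the limits is an extreme value; points exactly on
#' a limit are not flagged. No run rules (Western Electric etc.) are applied
#' -- plain 3-sigma individuals charts only.
#'
#' @name spc_charts
NULL

#' Compute stable-period control limits
#'
#' @param series a [daily_series()].
#' @param stable a `stable_period` from [select_stable_period()], or any
#'   list with `start_day` / `end_day`.
#' @param min_n minimum non-missing stable-period values required (floor).
#' @return a `control_limits` object (`variable`, `center`, `sd`, `ucl`,
#'   `lcl`, `n`), or `NULL` with a warning when the stable-period SD is zero
#'   (degenerate chart, suppressed) or too few values are present.
#' @export
compute_limits <- function(series, stable, min_n = 10L) {
  v <- as_daily_values(series)[stable$start_day:stable$end_day]
  v <- v[!is.na(v)]
  if (length(v) < min_n) {
    warning("chart for '", series$name, "' suppressed: only ", length(v),
            " non-missing stable-period values (< ", min_n, ")", call. = FALSE)
    return(NULL)
  }
  center <- mean(v)
  s <- stats::sd(v)
  if (s == 0) {
    warning("chart for '", series$name,
            "' suppressed: zero stable-period SD", call. = FALSE)
    return(NULL)
  }
  structure(list(variable = series$name, center = center, sd = s,
                 ucl = center + 3 * s, lcl = center - 3 * s,
                 n = length(v)),
            class = "control_limits")
}

#' @export
print.control_limits <- function(x, ...) {
  cat(sprintf("<control_limits> %s: center %.3f, LCL %.3f, UCL %.3f (n=%d)\n",
              x$variable, x$center, x$lcl, x$ucl, x$n))
  invisible(x)
}

#' Flag extreme values against control limits
#'
#' @param series a [daily_series()].
#' @param limits a `control_limits` object.
#' @param window day interval `c(from, to)` to scan; defaults to the whole
#'   series.
#' @return data.frame of extreme values, one row per flagged day, sorted by
#'   day: `variable`, `day`, `value`, `direction` (`"increase"` when value >
#'   UCL, `"decrease"` when value < LCL), `magnitude_sd` = |value - center|
#'   / SD (> 3 by construction).
#' @export
flag_extremes <- function(series, limits,
                          window = c(1L, series$study_days)) {
  v <- as_daily_values(series)
  stopifnot(window[1] >= 1L, window[2] <= length(v), window[1] <= window[2])
  days <- window[1]:window[2]
  x <- v[days]
  hi <- !is.na(x) & x > limits$ucl
  lo <- !is.na(x) & x < limits$lcl
  flagged <- hi | lo
  data.frame(
    variable = rep(limits$variable, sum(flagged)),
    day = days[flagged],
    value = x[flagged],
    direction = ifelse(hi[flagged], "increase", "decrease"),
    magnitude_sd = abs(x[flagged] - limits$center) / limits$sd,
    stringsAsFactors = FALSE
  )
}

#' Per-variable chart table
#'
#' Renders the full individuals chart as a plain table (one row per day):
#' value, center line, limits, flag and direction -- the tabular equivalent
#' of the classic control-chart figure.
#'
#' @inheritParams flag_extremes
#' @return data.frame with columns `day`, `value`, `center`, `ucl`, `lcl`,
#'   `flag`, `direction`, `magnitude_sd`.
#' @export
chart_table <- function(series, limits, window = c(1L, series$study_days)) {
  v <- as_daily_values(series)
  days <- window[1]:window[2]
  x <- v[days]
  dir <- rep(NA_character_, length(x))
  dir[!is.na(x) & x > limits$ucl] <- "increase"
  dir[!is.na(x) & x < limits$lcl] <- "decrease"
  data.frame(day = days, value = x,
             center = limits$center, ucl = limits$ucl, lcl = limits$lcl,
             flag = !is.na(dir), direction = dir,
             magnitude_sd = ifelse(is.na(dir), NA_real_,
                                   abs(x - limits$center) / limits$sd),
             stringsAsFactors = FALSE)
}
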