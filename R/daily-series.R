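#' Daily study series
#'
#' A `daily_series` is a named variable indexed by study day `1..study_days`,
#' with `NA` for missing days. It is the unit on which all control-chart and
#' changepoint analysis operates.
#'
#' @param name variable identifier (e.g. `"sleep_duration"`, `"lc_self"`).
#' @param values numeric vector of length `study_days`; `NA` allowed.
#' @param study_days number of study days; defaults to `length(values)`.
#' @return an object of class `daily_series`.
#' @export
daily_series <- function(name, values, study_days = length(values)) {
  stopifnot(is.character(name), length(name) == 1L)
  values <- as.numeric(values)
  if (length(values) != study_days)
    stop("values must have length study_days (", study_days, ")", call. = FALSE)
  if (any(!is.finite(values) & !is.na(values)))
    stop("values must be finite where present", call. = FALSE)
  structure(list(name = name, values = values, study_days = study_days),
            class = "daily_series")
}

#' @export
print.daily_series <- function(x, ...) {
  cat("<daily_series> ", x$name, ": ", x$study_days, " days, ",
      sum(!is.na(x$values)), " present\n", sep = "")
  invisible(x)
}

#' @export
length.daily_series <- function(x) x$study_days

as_daily_values <- function(x) {
  if (inherits(x, "daily_series")) x$values else as.numeric(x)
}

#' Read / write a daily series as CSV
#'
#' Plain two-column CSV (`study_day,value`), empty cells for missing days.
#'
#' @param x a `daily_series`.
#' @param path file path.
#' @param name variable name to attach on read.
#' @export
write_daily_series <- function(x, path) {
  utils::write.csv(data.frame(study_day = seq_len(x$study_days),
                              value = x$values),
                   path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_daily_series
#' @export
read_daily_series <- function(path, name) {
  d <- utils::read.csv(path)
  daily_series(name, d$value[order(d$study_day)])
}

# days covered by 1-based study week w: 7(w-1)+1 .. 7w
week_days <- function(w) (7L * (w - 1L) + 1L):(7L * w)

day_to_week <- function(day) ((as.integer(day) - 1L) %/% 7L) + 1L
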