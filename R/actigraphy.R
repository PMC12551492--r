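#' Actigraphy sleep scoring
#'
#' Nightly sleep variables are scored from epoch-level activity counts
#' (wrist actigraphy, 60-s epochs by default) guided by a morning sleep
#' diary. The diary defines the rest period (lights-off to get-up); within
#' it, each epoch is classified sleep/wake by a Cole-Kripke-style weighted
#' moving window over counts; sleep onset and offset are anchored on runs of
#' consecutive sleep-scored minutes; and the derived variables follow the
#' conventions: duration = onset-to-offset minutes (WASO counted within it),
#' SOL = lights-off to onset, efficiency = minutes asleep / minutes in bed,
#' WASO = wake minutes strictly between onset and offset.
#'
#' @name actigraphy_sleep
NULL

#' Epoch activity series
#'
#' @param start_time start of the recording, hours on the noon-anchored
#'   timeline of its first night (see [clock_to_timeline()]).
#' @param epoch_seconds epoch length in seconds (default 60).
#' @param counts non-negative activity counts, one per epoch; `NA` =
#'   missing epoch.
#' @return an `epoch_series`.
#' @export
epoch_series <- function(start_time, counts, epoch_seconds = 60) {
  counts <- as.numeric(counts)
  if (any(counts < 0, na.rm = TRUE))
    stop("activity counts must be non-negative", call. = FALSE)
  structure(list(start_time = start_time, epoch_seconds = epoch_seconds,
                 counts = counts),
            class = "epoch_series")
}

# timeline hour of the start of epoch i (1-based)
epoch_time <- function(e, i) e$start_time + (i - 1) * e$epoch_seconds / 3600

#' Sleep diary entry
#'
#' @param date calendar day of the morning (any comparable scalar; integer
#'   study day in the synthetic cohort).
#' @param lights_off,try_sleep,get_up clock times (`"HH:MM"` or timeline
#'   hours); `lights_off <= try_sleep` on the continuous timeline, `get_up`
#'   after `try_sleep`.
#' @param reported_sol_min self-reported minutes to fall asleep.
#' @param rating ordinal night rating.
#' @return a `sleep_diary_entry` with times stored as noon-anchored
#'   timeline hours.
#' @export
sleep_diary_entry <- function(date, lights_off, try_sleep = lights_off,
                              reported_sol_min = NA_real_, get_up,
                              rating = NA_integer_) {
  lo <- if (is.character(lights_off)) clock_to_timeline(lights_off) else lights_off
  ts <- if (is.character(try_sleep)) clock_to_timeline(try_sleep) else try_sleep
  gu <- if (is.character(get_up)) clock_to_timeline(get_up) else get_up
  if (lo > ts) stop("lights_off must not be after try_sleep", call. = FALSE)
  if (gu <= ts) stop("get_up must be after try_sleep", call. = FALSE)
  structure(list(date = date, lights_off = lo, try_sleep = ts,
                 reported_sol_min = reported_sol_min, get_up = gu,
                 rating = rating),
            class = "sleep_diary_entry")
}

#' Select the diary-defined rest period
#'
#' Returns the `[lights_off, get_up]` interval snapped outward to epoch
#' boundaries. The night is flagged unscorable when more than
#' `missing_tolerance` of the epochs in the window are missing.
#'
#' @param epochs an [epoch_series()] covering the night.
#' @param diary a [sleep_diary_entry()].
#' @param missing_tolerance maximum tolerated fraction of missing epochs in
#'   the rest window (default 0.2).
#' @return list with `start`, `end` (timeline hours), `epoch_idx` (indices
#'   into `epochs$counts`), and `unscorable` flag.
#' @export
detect_rest_period <- function(epochs, diary, missing_tolerance = 0.2) {
  dt <- epochs$epoch_seconds / 3600
  first <- floor((diary$lights_off - epochs$start_time) / dt + 1e-9) + 1L
  last <- ceiling((diary$get_up - epochs$start_time) / dt - 1e-9)
  if (first < 1L || last > length(epochs$counts))
    stop("epoch data do not cover the diary night", call. = FALSE)
  idx <- first:last
  frac_missing <- mean(is.na(epochs$counts[idx]))
  list(start = epoch_time(epochs, first),
       end = epoch_time(epochs, last + 1L),
       epoch_idx = idx,
       unscorable = frac_missing > missing_tolerance)
}

#' Score epochs sleep / wake
#'
#' A weighted moving window over counts: for epoch t the score is
#' `S = sum_k w_k * c[t+k]`, k in -2..2, default weights
#' `(0.04, 0.20, 1.00, 0.20, 0.04)`; the epoch is wake when `S >
#' wake_threshold` (default 40 counts), else sleep. Missing epochs
#' contribute zero to neighbours' scores and are themselves scored from the
#' remaining window.
#'
#' @param counts activity counts within the rest window (1-min epochs).
#' @param weights symmetric weight vector, centre in the middle.
#' @param wake_threshold wake decision threshold on the weighted sum.
#' @return character vector `"sleep"` / `"wake"`, one per epoch.
#' @export
score_sleep_wake <- function(counts,
                             weights = c(0.04, 0.20, 1.00, 0.20, 0.04),
                             wake_threshold = 40) {
  stopifnot(length(weights) %% 2 == 1)
  half <- (length(weights) - 1L) %/% 2L
  c0 <- ifelse(is.na(counts), 0, counts)
  padded <- c(rep(0, half), c0, rep(0, half))
  n <- length(counts)
  s <- numeric(n)
  for (k in seq_along(weights))
    s <- s + weights[k] * padded[seq.int(k, length.out = n)]
  ifelse(s > wake_threshold, "wake", "sleep")
}

#' Summarise one scored night
#'
#' Sleep onset is the start of the first run of at least `onset_run_min`
#' consecutive sleep-scored minutes after rest start; offset is the end of
#' the last such run before rest end. Derived variables: `sol_min` =
#' minutes from the SOL reference (lights-off by default, try-to-sleep via
#' `sol_reference`) to onset; `waso_min` = wake-scored minutes strictly
#' between onset and offset; `duration_min` = minutes between onset and
#' offset; `efficiency` = (duration - WASO) / minutes in bed (lights-off to
#' get-up); `midsleep` = onset + (offset - onset)/2.
#'
#' @param scored output of [score_sleep_wake()] for the rest-window epochs.
#' @param rest output of [detect_rest_period()].
#' @param diary the [sleep_diary_entry()].
#' @param epoch_seconds epoch length (must be 60 for minute-run rules).
#' @param onset_run_min run length in minutes defining onset/offset.
#' @param sol_reference `"lights_off"` or `"try_sleep"`.
#' @return a `sleep_night` (list) or `NULL` when the night is unscorable
#'   (no qualifying sleep run, or the rest window failed the missing-epoch
#'   tolerance).
#' @export
summarize_night <- function(scored, rest, diary, epoch_seconds = 60,
                            onset_run_min = 10L,
                            sol_reference = c("lights_off", "try_sleep")) {
  sol_reference <- match.arg(sol_reference)
  if (isTRUE(rest$unscorable)) return(NULL)
  ep_min <- epoch_seconds / 60
  sleep <- scored == "sleep"
  r <- rle(sleep)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  q <- r$values & (r$lengths * ep_min) >= onset_run_min
  if (!any(q)) return(NULL)
  onset_ep <- starts[which(q)[1L]]
  offset_ep <- ends[which(q)[sum(q)]]
  onset <- rest$start + (onset_ep - 1L) * ep_min / 60
  offset <- rest$start + offset_ep * ep_min / 60
  inside <- seq_along(scored) > onset_ep & seq_along(scored) < offset_ep
  waso_min <- sum(!sleep & inside) * ep_min
  duration_min <- (offset - onset) * 60
  sol_ref <- if (sol_reference == "lights_off") diary$lights_off else diary$try_sleep
  sol_min <- max(0, (onset - sol_ref) * 60)
  in_bed_min <- (diary$get_up - diary$lights_off) * 60
  structure(list(
    date = diary$date,
    rest_start = rest$start, rest_end = rest$end,
    onset = onset, offset = offset,
    duration_min = duration_min,
    sol_min = sol_min,
    efficiency = (duration_min - waso_min) / in_bed_min,
    waso_min = waso_min,
    midsleep = onset + (offset - onset) / 2,
    cpd = NA_real_
  ), class = "sleep_night")
}

#' Score a full night from epochs + diary
#'
#' Convenience wrapper chaining [detect_rest_period()],
#' [score_sleep_wake()] and [summarize_night()].
#'
#' @inheritParams detect_rest_period
#' @inheritParams summarize_night
#' @param ... passed to [score_sleep_wake()].
#' @return a `sleep_night` or `NULL` (unscorable).
#' @export
score_night <- function(epochs, diary, missing_tolerance = 0.2,
                        onset_run_min = 10L,
                        sol_reference = "lights_off", ...) {
  rest <- detect_rest_period(epochs, diary, missing_tolerance)
  if (rest$unscorable) return(NULL)
  scored <- score_sleep_wake(epochs$counts[rest$epoch_idx], ...)
  summarize_night(scored, rest, diary, epochs$epoch_seconds,
                  onset_run_min, sol_reference)
}

#' Composite phase deviation (CPD)
#'
#' Daily circadian misalignment combining mistiming (distance of tonight's
#' midsleep from the chronotype-ideal midsleep) and irregularity (distance
#' from last night's midsleep): `cpd = sqrt(mistiming^2 + irregularity^2)`,
#' in hours. When the previous night is missing the irregularity term is
#' zero (mistiming-only), keeping the first study night defined.
#'
#' @param midsleep_today tonight's midsleep, timeline hours.
#' @param midsleep_yesterday last night's midsleep, or `NA`.
#' @param ideal_midsleep chronotype reference midsleep (clock time or
#'   timeline hours).
#' @return CPD in hours.
#' @export
compute_cpd <- function(midsleep_today, midsleep_yesterday, ideal_midsleep) {
  if (is.character(ideal_midsleep))
    ideal_midsleep <- clock_to_timeline(ideal_midsleep)
  mistiming <- midsleep_today - ideal_midsleep
  irregularity <- if (is.na(midsleep_yesterday)) 0
    else midsleep_today - midsleep_yesterday
  sqrt(mistiming^2 + irregularity^2)
}

#' Nightly records to the seven daily sleep series
#'
#' @param nights list of `sleep_night` objects (or `NULL` for unscorable
#'   nights), sorted by date; `date` must be the integer study day.
#' @param study_days length of the study.
#' @param ideal_midsleep chronotype reference for the CPD series.
#' @return named list of seven [daily_series()]: `sleep_onset`,
#'   `sleep_offset`, `sleep_efficiency`, `sleep_duration`, `sol`, `waso`,
#'   `cpd`. Unscorable nights are missing days.
#' @export
nights_to_daily_series <- function(nights, study_days = 180L,
                                   ideal_midsleep = "03:30") {
  nights <- Filter(Negate(is.null), nights)
  days <- vapply(nights, function(n) as.integer(n$date), integer(1))
  if (anyDuplicated(days))
    stop("duplicate night dates: ", paste(days[duplicated(days)],
                                          collapse = ", "), call. = FALSE)
  grab <- function(field) {
    v <- rep(NA_real_, study_days)
    v[days] <- vapply(nights, function(n) n[[field]], numeric(1))
    v
  }
  onset <- grab("onset"); offset <- grab("offset")
  midsleep <- grab("midsleep")
  cpd <- rep(NA_real_, study_days)
  for (d in seq_len(study_days)) {
    if (is.na(midsleep[d])) next
    prev <- if (d > 1L) midsleep[d - 1L] else NA_real_
    cpd[d] <- compute_cpd(midsleep[d], prev, ideal_midsleep)
  }
  list(
    sleep_onset = daily_series("sleep_onset", onset),
    sleep_offset = daily_series("sleep_offset", offset),
    sleep_efficiency = daily_series("sleep_efficiency", grab("efficiency")),
    sleep_duration = daily_series("sleep_duration", grab("duration_min")),
    sol = daily_series("sol", grab("sol_min")),
    waso = daily_series("waso", grab("waso_min")),
    cpd = daily_series("cpd", cpd)
  )
}

#' The seven sleep-variable names
#' @return character vector of the sleep variables analysed per night.
#' @export
sleep_variables <- function() {
  c("sleep_onset", "sleep_offset", "sleep_efficiency", "sleep_duration",
    "sol", "waso", "cpd")
}

#' Read / write epoch activity and nightly tables as CSV
#'
#' Epoch CSV columns: `timestamp` (ISO-8601), `counts`. Night-table CSV:
#' one row per scored night with all sleep variables.
#'
#' @param epochs an [epoch_series()].
#' @param path file path.
#' @param origin POSIXct anchor for epoch 1 (timeline hour 0 = the noon
#'   preceding night 1).
#' @export
write_epoch_csv <- function(epochs, path,
                            origin = as.POSIXct("2024-01-01 12:00:00",
                                                tz = "UTC")) {
  t <- origin + (epochs$start_time * 3600) +
    (seq_along(epochs$counts) - 1L) * epochs$epoch_seconds
  utils::write.csv(data.frame(
    timestamp = format(t, "%Y-%m-%dT%H:%M:%S"),
    counts = epochs$counts), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_epoch_csv
#' @export
read_epoch_csv <- function(path,
                           origin = as.POSIXct("2024-01-01 12:00:00",
                                               tz = "UTC")) {
  d <- utils::read.csv(path)
  t <- as.POSIXct(d$timestamp, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  dt <- as.numeric(difftime(t[2], t[1], units = "secs"))
  if (length(t) > 2 && any(abs(diff(as.numeric(t)) - dt) > 1e-6))
    stop("epoch timestamps must be evenly spaced", call. = FALSE)
  epoch_series(start_time = as.numeric(difftime(t[1], origin,
                                                units = "hours")),
               counts = d$counts, epoch_seconds = dt)
}

#' @param nights list of `sleep_night` objects.
#' @rdname write_epoch_csv
#' @export
write_night_table <- function(nights, path) {
  nights <- Filter(Negate(is.null), nights)
  tab <- do.call(rbind, lapply(nights, function(n)
    data.frame(date = n$date, rest_start = n$rest_start,
               rest_end = n$rest_end, onset = n$onset, offset = n$offset,
               duration_min = n$duration_min, sol_min = n$sol_min,
               efficiency = n$efficiency, waso_min = n$waso_min,
               midsleep = n$midsleep)))
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
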