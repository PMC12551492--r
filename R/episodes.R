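#' Mood-episode detection and stable-period selection
#'
#' Manic and depressive episodes are operationalised from weekly self-report
#' scales plus the daily Life Chart self-rating (LC-self, 0-100 VAS with 50
#' as the midline):
#'
#' * manic: ASRM > 5 on at least two consecutive weeks, and LC-self > 50 on
#'   at least 75% of (non-missing) days within those weeks;
#' * depressive: IDS-SR > 25 on at least three consecutive weeks, and
#'   LC-self < 50 on at least 75% of days within those weeks.
#'
#' Week `w` covers study days `7(w-1)+1 .. 7w`; because the weekly scales
#' rate the past week, the first qualifying week is the week the episode
#' started. The two weeks before the start week are the prodromal phase.
#'
#' @name episodes
NULL

#' Weekly symptom-scale table
#'
#' @param week_index 1-based week of study.
#' @param asrm Altman Self-Rating Mania totals, integer 0-20.
#' @param ids_sr IDS-SR totals, integer 0-84.
#' @return data.frame with columns `week_index`, `asrm`, `ids_sr`.
#' @export
weekly_scales <- function(week_index, asrm, ids_sr) {
  stopifnot(length(week_index) == length(asrm),
            length(asrm) == length(ids_sr))
  if (any(asrm < 0 | asrm > 20, na.rm = TRUE))
    stop("asrm must be within [0, 20]", call. = FALSE)
  if (any(ids_sr < 0 | ids_sr > 84, na.rm = TRUE))
    stop("ids_sr must be within [0, 84]", call. = FALSE)
  d <- data.frame(week_index = as.integer(week_index),
                  asrm = as.numeric(asrm), ids_sr = as.numeric(ids_sr))
  d[order(d$week_index), , drop = FALSE]
}

#' An episode interval with its prodromal window
#'
#' @param polarity `"manic"` or `"depressive"`.
#' @param qualifying_weeks contiguous week indices meeting the scale rule.
#' @return an `episode_interval`: `start_week`, `start_day` (first day of the
#'   start week), `prodrome` = `[start_day - 14, start_day - 1]` (clipped at
#'   study day 1 for episodes starting before week 3),
#'   `start_week_days` = `[start_day, start_day + 6]`, and `end_day` (last
#'   day of the last qualifying week).
#' @export
episode_interval <- function(polarity, qualifying_weeks) {
  polarity <- match.arg(polarity, c("manic", "depressive"))
  qualifying_weeks <- as.integer(qualifying_weeks)
  stopifnot(length(qualifying_weeks) >= 1L,
            all(diff(qualifying_weeks) == 1L))
  start_week <- qualifying_weeks[1L]
  start_day <- 7L * (start_week - 1L) + 1L
  structure(list(
    polarity = polarity,
    qualifying_weeks = qualifying_weeks,
    start_week = start_week,
    start_day = start_day,
    prodrome = c(max(1L, start_day - 14L), start_day - 1L),
    start_week_days = c(start_day, start_day + 6L),
    end_day = 7L * qualifying_weeks[length(qualifying_weeks)]
  ), class = "episode_interval")
}

#' @export
print.episode_interval <- function(x, ...) {
  cat("<episode_interval> ", x$polarity, ": weeks ",
      x$qualifying_weeks[1], "-", max(x$qualifying_weeks),
      " (start day ", x$start_day, ", prodrome days ",
      x$prodrome[1], "-", x$prodrome[2], ")\n", sep = "")
  invisible(x)
}

# maximal runs of TRUE of length >= min_len; returns list of index vectors
maximal_runs <- function(flag, min_len) {
  flag[is.na(flag)] <- FALSE
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  Map(seq.int, starts[keep], ends[keep])
}

# fraction of non-missing LC days in the given weeks on the qualifying side
lc_fraction <- function(lc, weeks, side) {
  v <- as_daily_values(lc)
  days <- unlist(lapply(weeks, week_days))
  days <- days[days <= length(v)]
  x <- v[days]
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_real_)
  if (side == "above") mean(x > 50) else mean(x < 50)
}

detect_episodes_one <- function(weekly, lc, polarity) {
  if (polarity == "manic") {
    elevated <- weekly$asrm > 5; min_weeks <- 2L; side <- "above"
  } else {
    elevated <- weekly$ids_sr > 25; min_weeks <- 3L; side <- "below"
  }
  runs <- maximal_runs(elevated, min_weeks)
  out <- list()
  for (idx in runs) {
    weeks <- weekly$week_index[idx]
    frac <- lc_fraction(lc, weeks, side)
    if (is.na(frac)) {
      message("episode candidate weeks ", weeks[1], "-", max(weeks),
              " rejected: all LC-self days missing")
      next
    }
    if (frac >= 0.75) out[[length(out) + 1L]] <- episode_interval(polarity, weeks)
  }
  out
}

#' Detect manic / depressive episodes
#'
#' @param weekly a [weekly_scales()] data.frame covering the study.
#' @param lc the LC-self [daily_series()] (0-100 VAS).
#' @return list of [episode_interval()] objects (possibly empty). Runs of
#'   elevated weeks are maximal; a candidate run qualifies only if the
#'   LC-self 75% rule holds over its weeks (denominator: non-missing days).
#' @export
detect_manic_episodes <- function(weekly, lc) {
  detect_episodes_one(weekly, lc, "manic")
}

#' @rdname detect_manic_episodes
#' @export
detect_depressive_episodes <- function(weekly, lc) {
  detect_episodes_one(weekly, lc, "depressive")
}

#' @rdname detect_manic_episodes
#' @export
detect_episodes <- function(weekly, lc) {
  c(detect_manic_episodes(weekly, lc), detect_depressive_episodes(weekly, lc))
}

#' Select the 35-day stable period before an episode
#'
#' Scans week-aligned 35-day (five-week) windows from day 1 forward and
#' returns the earliest window that (a) contains no week belonging to a run
#' of two consecutive weeks with ASRM > 5 or IDS-SR > 25 (with
#' `strict = TRUE`, no single elevated week at all), (b) has lower LC-self
#' variability (SD) than the full study, and (c) ends at least two weeks
#' before the episode start day (`end_day <= start_day - 15`).
#'
#' @param weekly a [weekly_scales()] data.frame.
#' @param lc the LC-self [daily_series()].
#' @param episode an [episode_interval()].
#' @param sleep_series optional named list of [daily_series()]; per-variable
#'   means and SDs over the window are attached when given.
#' @param strict logical; use the strict no-elevated-week reading.
#' @return a `stable_period` (`start_day`, `end_day`, `stats`) or `NULL`
#'   when no window qualifies (the patient is then excluded upstream).
#' @export
select_stable_period <- function(weekly, lc, episode, sleep_series = list(),
                                 strict = FALSE) {
  lcv <- as_daily_values(lc)
  sd_full <- stats::sd(lcv, na.rm = TRUE)
  latest_end <- episode$start_day - 15L
  if (latest_end < 35L) return(NULL)
  a <- weekly$asrm > 5; i <- weekly$ids_sr > 25
  # a week is symptomatic when it belongs to an episode-defining run of two
  # consecutive elevated weeks (strict mode: any elevated week at all)
  sympt_week <- weekly$week_index[
    if (strict) which(a | i) else which(in_consecutive_pair(a) |
                                          in_consecutive_pair(i))]
  for (start_day in seq(1L, latest_end - 34L, by = 7L)) {
    end_day <- start_day + 34L
    if (end_day > latest_end) break
    weeks <- day_to_week(start_day):day_to_week(end_day)
    if (!all(weeks %in% weekly$week_index)) next
    if (any(weeks %in% sympt_week)) next
    win <- lcv[start_day:end_day]
    if (!is.finite(sd_full) || !is.finite(stats::sd(win, na.rm = TRUE)) ||
        !(stats::sd(win, na.rm = TRUE) < sd_full)) next
    stats_tab <- NULL
    if (length(sleep_series)) {
      stats_tab <- do.call(rbind, lapply(names(sleep_series), function(nm) {
        v <- as_daily_values(sleep_series[[nm]])[start_day:end_day]
        data.frame(variable = nm, mean = mean(v, na.rm = TRUE),
                   sd = stats::sd(v, na.rm = TRUE),
                   n = sum(!is.na(v)))
      }))
    }
    return(structure(list(start_day = start_day, end_day = end_day,
                          stats = stats_tab),
                     class = "stable_period"))
  }
  NULL
}

# weeks that are part of a pair of consecutive TRUE flags
in_consecutive_pair <- function(flag) {
  flag[is.na(flag)] <- FALSE
  n <- length(flag)
  if (n < 2L) return(rep(FALSE, n))
  pair <- flag[-n] & flag[-1]
  c(pair, FALSE) | c(FALSE, pair)
}

#' @export
print.stable_period <- function(x, ...) {
  cat("<stable_period> days ", x$start_day, "-", x$end_day, "\n", sep = "")
  invisible(x)
}

#' Read / write weekly scales as CSV
#' @param weekly a [weekly_scales()] data.frame.
#' @param path file path.
#' @export
write_weekly_scales <- function(weekly, path) {
  utils::write.csv(weekly, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_weekly_scales
#' @export
read_weekly_scales <- function(path) {
  d <- utils::read.csv(path)
  weekly_scales(d$week_index, d$asrm, d$ids_sr)
}
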