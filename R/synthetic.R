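#' Synthetic single-case cohort generator
#'
#' Generates per-patient 180-day datasets with the statistical structure the
#' analysis pipeline assumes: daily Gaussian sleep variables, a daily mood
#' EMA (LC-self plus ten VAS mood items), weekly ASRM / IDS-SR totals, a
#' morning sleep diary, and -- on demand -- epoch-level activity counts.
#' Episodes and sleep disturbances are scripted, so every generated dataset
#' carries exact ground truth for recovery testing. By construction,
#' scripted episode weeks satisfy the episode thresholds (ASRM > 5 for
#' manic weeks, IDS-SR > 25 for depressive weeks, LC-self on the qualifying
#' side of the midline on ~90% of episode days) and non-episode weeks do
#' not.
#'
#' @name synthetic_data
NULL

#' Default per-variable baselines
#'
#' Daily sleep variables are Gaussian draws around these means/SDs (times
#' in noon-anchored timeline hours, durations in minutes, efficiency as a
#' fraction); EMA items are on the 0-100 VAS scale.
#'
#' @return named list of `c(mean, sd)` pairs.
#' @export
default_baseline_params <- function() {
  list(
    sleep_onset = c(mean = 11.5, sd = 0.75),     # 23:30
    sleep_offset = c(mean = 19.5, sd = 0.75),    # 07:30
    sleep_efficiency = c(mean = 0.88, sd = 0.04),
    sleep_duration = c(mean = 450, sd = 45),
    sol = c(mean = 20, sd = 10),
    waso = c(mean = 30, sd = 15),
    cpd = c(mean = 1.0, sd = 0.5),
    lc_self = c(mean = 50, sd = 6),
    mood_item = c(mean = 30, sd = 10),
    asrm = c(mean = 2, sd = 1.5),
    ids_sr = c(mean = 12, sd = 5)
  )
}

#' Default mood-item names
#'
#' Ten generic bipolar EMA items covering elevated and lowered mood.
#' @return character vector.
#' @export
default_mood_items <- function() {
  c("down", "excited", "satisfied", "irritable", "energetic",
    "worrying", "restless", "cheerful", "gloomy", "racing_thoughts")
}

#' Scripted episode / injection / cohort configuration
#'
#' @param patient patient id (integer).
#' @param polarity `"manic"` or `"depressive"`.
#' @param start_week 1-based study week in which the episode starts; must
#'   leave room for a 35-day stable period ending at least two weeks before
#'   the start (`start_week >= 8`).
#' @param duration_weeks episode length; >= 2 for manic, >= 3 for
#'   depressive (so the weekly scales can satisfy the episode criteria).
#' @return an `episode_script`.
#' @export
episode_script <- function(patient, polarity, start_week, duration_weeks) {
  polarity <- match.arg(polarity, c("manic", "depressive"))
  min_dur <- if (polarity == "manic") 2L else 3L
  if (duration_weeks < min_dur)
    stop("duration_weeks must be >= ", min_dur, " for a ", polarity,
         " episode", call. = FALSE)
  structure(list(patient = as.integer(patient), polarity = polarity,
                 start_week = as.integer(start_week),
                 duration_weeks = as.integer(duration_weeks)),
            class = "episode_script")
}

#' @param variable one of [sleep_variables()].
#' @param day study day of the injected change.
#' @param kind `"mean_shift"` (persists from `day` until the episode end,
#'   or study end if none) or `"extreme_value"` (single day).
#' @param magnitude signed size in stable-period SD units.
#' @rdname episode_script
#' @export
injection_script <- function(patient, variable, day, kind, magnitude) {
  kind <- match.arg(kind, c("mean_shift", "extreme_value"))
  if (!variable %in% sleep_variables())
    stop("unknown sleep variable: ", variable, call. = FALSE)
  structure(list(patient = as.integer(patient), variable = variable,
                 day = as.integer(day), kind = kind,
                 magnitude = as.numeric(magnitude)),
            class = "injection_script")
}

#' @param n_patients cohort size.
#' @param study_days study length in days (>= 49; default 180).
#' @param epoch_seconds actigraphy epoch length (default 60).
#' @param episode_scripts list of [episode_script()].
#' @param injection_scripts list of [injection_script()].
#' @param baseline_params see [default_baseline_params()].
#' @param missing_rate daily probability of a missing value in each sleep
#'   and mood series (default 0).
#' @param seed RNG seed; identical config + seed gives identical output.
#' @rdname episode_script
#' @export
cohort_config <- function(n_patients, study_days = 180L, epoch_seconds = 60,
                          episode_scripts = list(),
                          injection_scripts = list(),
                          baseline_params = default_baseline_params(),
                          missing_rate = 0, seed = 1L) {
  if (study_days < 49L)
    stop("study_days must be >= 49 (one stable period + prodrome + episode)",
         call. = FALSE)
  sds <- vapply(baseline_params, function(p) p[["sd"]], numeric(1))
  if (any(sds < 0)) stop("all baseline SDs must be >= 0", call. = FALSE)
  for (nm in c("lc_self", "mood_item")) {
    m <- baseline_params[[nm]][["mean"]]
    if (m < 0 || m > 100)
      stop("EMA baseline means must lie in [0, 100]", call. = FALSE)
  }
  for (s in episode_scripts) {
    start_day <- 7L * (s$start_week - 1L) + 1L
    if (start_day - 15L < 35L)
      stop("episode for patient ", s$patient, " starts on day ", start_day,
           ": too close to day 1 to leave a 35-day stable period ending ",
           "at least 14 days before the episode (start_week must be >= 8)",
           call. = FALSE)
    if (7L * (s$start_week + s$duration_weeks - 1L) > study_days)
      stop("episode for patient ", s$patient, " runs past the study end",
           call. = FALSE)
  }
  structure(list(n_patients = as.integer(n_patients),
                 study_days = as.integer(study_days),
                 epoch_seconds = epoch_seconds,
                 episode_scripts = episode_scripts,
                 injection_scripts = injection_scripts,
                 baseline_params = baseline_params,
                 missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Inject a scripted change into a daily series
#'
#' `mean_shift` adds `magnitude * stable_sd` to every day from
#' `script$day` to `end_day`. `extreme_value` sets the single day to
#' `baseline_mean + magnitude * stable_sd`, so the scripted magnitude is
#' the exact deviation from the series' stable level.
#'
#' @param series a [daily_series()].
#' @param script an [injection_script()].
#' @param stable_sd the stable-period SD in which `magnitude` is expressed.
#' @param baseline_mean stable level; defaults to the mean of the first 35
#'   days of the series.
#' @param end_day last day of a mean shift (default: end of series).
#' @return the modified [daily_series()].
#' @export
inject_change <- function(series, script, stable_sd,
                          baseline_mean = mean(series$values[1:35],
                                               na.rm = TRUE),
                          end_day = series$study_days) {
  stopifnot(stable_sd > 0)
  if (!script$variable %in% sleep_variables())
    stop("unknown sleep variable: ", script$variable, call. = FALSE)
  if (script$day < 1L || script$day > series$study_days)
    stop("injection day outside the series range", call. = FALSE)
  v <- series$values
  if (script$kind == "mean_shift") {
    idx <- script$day:min(end_day, series$study_days)
    v[idx] <- v[idx] + script$magnitude * stable_sd
  } else {
    v[script$day] <- baseline_mean + script$magnitude * stable_sd
  }
  daily_series(series$name, v, series$study_days)
}

clip01 <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Generate a synthetic cohort
#'
#' @param config a [cohort_config()].
#' @return a `synthetic_cohort`: `config` plus `patients`, a list where
#'   each element holds `sleep` (the seven daily sleep series), `mood`
#'   (`lc_self` plus the mood items), `weekly` (a [weekly_scales()] table),
#'   `diary` (one [sleep_diary_entry()] per night, consistent with the
#'   sleep series), and `ground_truth` (scripted episodes, injected change
#'   days, nightly rest windows).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  bp <- config$baseline_params
  nd <- config$study_days
  n_weeks <- nd %/% 7L
  patients <- vector("list", config$n_patients)

  for (p in seq_len(config$n_patients)) {
    epis <- Filter(function(s) s$patient == p, config$episode_scripts)
    injs <- Filter(function(s) s$patient == p, config$injection_scripts)

    # --- daily sleep variables: Gaussian baselines -----------------------
    sleep <- lapply(sleep_variables(), function(nm) {
      prm <- bp[[nm]]
      daily_series(nm, stats::rnorm(nd, prm[["mean"]], prm[["sd"]]))
    })
    names(sleep) <- sleep_variables()

    # episode day masks
    ep_days <- rep(FALSE, nd); ep_polarity <- rep(NA_character_, nd)
    for (s in epis) {
      d0 <- 7L * (s$start_week - 1L) + 1L
      d1 <- 7L * (s$start_week + s$duration_weeks - 1L)
      ep_days[d0:d1] <- TRUE
      ep_polarity[d0:d1] <- s$polarity
    }

    # --- injections (magnitudes in true baseline SD units) ---------------
    for (s in injs) {
      prm <- bp[[s$variable]]
      end_day <- nd
      for (e in epis) {
        d1 <- 7L * (e$start_week + e$duration_weeks - 1L)
        if (s$day <= d1) { end_day <- d1; break }
      }
      sleep[[s$variable]] <- inject_change(
        sleep[[s$variable]], s, stable_sd = prm[["sd"]],
        baseline_mean = prm[["mean"]], end_day = end_day)
    }

    # --- daily mood: LC-self + items --------------------------------------
    lc <- stats::rnorm(nd, bp$lc_self[["mean"]], bp$lc_self[["sd"]])
    qualifies <- stats::runif(nd) < 0.9   # margin above the 75% rule
    manic_day <- ep_days & ep_polarity == "manic"
    depr_day <- ep_days & ep_polarity == "depressive"
    lc[manic_day] <- ifelse(qualifies[manic_day],
                            stats::runif(sum(manic_day), 60, 90),
                            stats::runif(sum(manic_day), 20, 50))
    lc[depr_day] <- ifelse(qualifies[depr_day],
                           stats::runif(sum(depr_day), 10, 40),
                           stats::runif(sum(depr_day), 50, 80))
    lc <- clip01(lc, 0, 100)

    items <- default_mood_items()
    item_sign <- stats::setNames(
      c(-1, 1, 1, 1, 1, -1, 1, 1, -1, 1), items) # direction of manic response
    mood <- list(lc_self = daily_series("lc_self", lc))
    for (it in items) {
      v <- stats::rnorm(nd, bp$mood_item[["mean"]], bp$mood_item[["sd"]])
      pol_sign <- ifelse(is.na(ep_polarity), 0,
                         ifelse(ep_polarity == "manic", 1, -1))
      v <- v + ep_days * pol_sign * item_sign[[it]] * 1.5 * bp$mood_item[["sd"]]
      mood[[it]] <- daily_series(it, clip01(v, 0, 100))
    }

    # --- weekly scales: clipped baseline + scripted bump ------------------
    asrm <- clip01(round(stats::rnorm(n_weeks, bp$asrm[["mean"]],
                                      bp$asrm[["sd"]])), 0, 5)
    ids <- clip01(round(stats::rnorm(n_weeks, bp$ids_sr[["mean"]],
                                     bp$ids_sr[["sd"]])), 0, 25)
    for (s in epis) {
      wk <- s$start_week:(s$start_week + s$duration_weeks - 1L)
      if (s$polarity == "manic")
        asrm[wk] <- clip01(round(stats::runif(length(wk), 8, 14)), 6, 20)
      else
        ids[wk] <- clip01(round(stats::runif(length(wk), 30, 45)), 26, 84)
    }
    weekly <- weekly_scales(seq_len(n_weeks), asrm, ids)

    # --- diary consistent with the sleep series ---------------------------
    onset <- sleep$sleep_onset$values
    offset <- sleep$sleep_offset$values
    sol <- pmax(sleep$sol$values, 0)
    diary <- lapply(seq_len(nd), function(d) {
      sleep_diary_entry(date = d,
                        lights_off = onset[d] - sol[d] / 60,
                        try_sleep = onset[d] - sol[d] / 60,
                        reported_sol_min = sol[d],
                        get_up = offset[d] + stats::runif(1, 5, 20) / 60,
                        rating = sample.int(5, 1))
    })

    # --- optional missingness --------------------------------------------
    if (config$missing_rate > 0) {
      for (nm in names(sleep)) {
        drop <- stats::runif(nd) < config$missing_rate
        v <- sleep[[nm]]$values; v[drop] <- NA
        sleep[[nm]] <- daily_series(nm, v)
      }
      for (nm in names(mood)) {
        drop <- stats::runif(nd) < config$missing_rate
        v <- mood[[nm]]$values; v[drop] <- NA
        mood[[nm]] <- daily_series(nm, v)
      }
    }

    patients[[p]] <- list(
      sleep = sleep, mood = mood, weekly = weekly, diary = diary,
      ground_truth = list(
        episodes = epis, injections = injs,
        rest_windows = data.frame(
          day = seq_len(nd),
          rest_start = onset[seq_len(nd)] - sol / 60,
          rest_end = offset[seq_len(nd)])
      ))
  }
  structure(list(config = config, patients = patients),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort> ", length(x$patients), " patients x ",
      x$config$study_days, " days\n", sep = "")
  invisible(x)
}

#' Generate one synthetic night of epoch activity
#'
#' Daytime epochs are drawn from a high-mean overdispersed count
#' distribution (negative binomial, variance = dispersion x mean), rest
#' epochs from a low-mean one, and scripted wake bouts inside the rest
#' window again from the high-mean one. The true onset/offset (the rest
#' window edges) and total bout minutes are recorded as ground truth.
#'
#' @param rest_window `c(start, end)` timeline hours within the 24-h day
#'   (noon to noon).
#' @param wake_bouts list of `c(start, end)` intervals inside the rest
#'   window; must not overlap.
#' @param params list with `day_mean`, `rest_mean`, `bout_mean` (counts per
#'   epoch), `dispersion` (variance/mean), `epoch_seconds`.
#' @param seed optional RNG seed for this night.
#' @return list with `epochs` (an [epoch_series()] spanning hours 0-24) and
#'   `truth` (`onset`, `offset`, `waso_min`).
#' @export
generate_epoch_night <- function(rest_window, wake_bouts = list(),
                                 params = list(day_mean = 250, rest_mean = 5,
                                               bout_mean = 250,
                                               dispersion = 2,
                                               epoch_seconds = 60),
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(rest_window[1] >= 0, rest_window[2] <= 24,
            rest_window[1] < rest_window[2])
  if (length(wake_bouts) > 1L) {
    b <- do.call(rbind, wake_bouts)
    b <- b[order(b[, 1]), , drop = FALSE]
    if (any(b[-1, 1] < b[-nrow(b), 2]))
      stop("wake bouts must not overlap", call. = FALSE)
  }
  for (b in wake_bouts)
    if (b[1] < rest_window[1] || b[2] > rest_window[2])
      stop("wake bouts must lie within the rest window", call. = FALSE)
  dt <- params$epoch_seconds / 3600
  n <- as.integer(round(24 / dt))
  t0 <- (seq_len(n) - 1L) * dt           # epoch start times
  mu <- rep(params$day_mean, n)
  in_rest <- t0 >= rest_window[1] & t0 < rest_window[2]
  mu[in_rest] <- params$rest_mean
  for (b in wake_bouts) {
    in_bout <- t0 >= b[1] & t0 < b[2]
    mu[in_bout] <- params$bout_mean
  }
  size <- mu / (params$dispersion - 1)   # var = dispersion * mu
  counts <- stats::rnbinom(n, size = size, mu = mu)
  list(epochs = epoch_series(start_time = 0, counts = counts,
                             epoch_seconds = params$epoch_seconds),
       truth = list(onset = rest_window[1], offset = rest_window[2],
                    waso_min = sum(vapply(wake_bouts,
                                          function(b) (b[2] - b[1]) * 60,
                                          numeric(1)))))
}

#' Write a synthetic cohort as plain CSV files
#'
#' Per patient `p`, writes `patient<p>_sleep_<var>.csv` (study_day, value),
#' `patient<p>_mood.csv` (long: study_day, item, value),
#' `patient<p>_weekly.csv`, `patient<p>_diary.csv` and a
#' `patient<p>_truth.txt` key-value sidecar with the scripted ground truth.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if absent).
#' @export
write_cohort_csv <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (p in seq_along(cohort$patients)) {
    pat <- cohort$patients[[p]]
    stem <- file.path(dir, sprintf("patient%d", p))
    for (nm in names(pat$sleep))
      write_daily_series(pat$sleep[[nm]], paste0(stem, "_sleep_", nm, ".csv"))
    mood_long <- do.call(rbind, lapply(names(pat$mood), function(nm)
      data.frame(study_day = seq_len(pat$mood[[nm]]$study_days),
                 item = nm, value = pat$mood[[nm]]$values)))
    utils::write.csv(mood_long, paste0(stem, "_mood.csv"),
                     row.names = FALSE, na = "")
    write_weekly_scales(pat$weekly, paste0(stem, "_weekly.csv"))
    diary_tab <- do.call(rbind, lapply(pat$diary, function(d)
      data.frame(date = d$date, lights_off = d$lights_off,
                 try_sleep = d$try_sleep,
                 reported_sol_min = d$reported_sol_min,
                 get_up = d$get_up, rating = d$rating)))
    utils::write.csv(diary_tab, paste0(stem, "_diary.csv"),
                     row.names = FALSE, na = "")
    gt <- pat$ground_truth
    lines <- c(
      vapply(gt$episodes, function(e)
        sprintf("episode: polarity=%s start_week=%d duration_weeks=%d",
                e$polarity, e$start_week, e$duration_weeks), character(1)),
      vapply(gt$injections, function(i)
        sprintf("injection: variable=%s day=%d kind=%s magnitude=%g",
                i$variable, i$day, i$kind, i$magnitude), character(1)))
    writeLines(lines, paste0(stem, "_truth.txt"))
  }
  invisible(dir)
}
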