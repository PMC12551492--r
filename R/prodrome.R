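#' Prodromal change analysis
#'
#' Combines Shewhart extreme values and changepoint mean shifts into the
#' headline single-case outputs: per-variable change labels in the
#' prodromal phase and the start week, a sleep-versus-mood temporal-order
#' verdict based on confidence-interval overlap, and a descriptive
#' prodromal-versus-stable event-rate comparison.
#'
#' Day windows are closed intervals of study days; an event on the episode
#' start day belongs to the start week, not the prodrome (the prodrome is
#' the two weeks *before* the start week).
#'
#' @name prodrome_analysis
NULL

#' Collect change events from chart and changepoint output
#'
#' @param extremes data.frame of extreme values (from [flag_extremes()],
#'   rows possibly from several variables).
#' @param shifts data.frame of mean shifts (from [detect_mean_shifts()]).
#' @param episode an [episode_interval()].
#' @param stable a `stable_period`.
#' @param streams named character vector mapping variable -> `"sleep"` or
#'   `"mood"`; defaults assign [sleep_variables()] to sleep and everything
#'   else must be listed explicitly.
#' @return day-sorted data.frame of events within the stable-start to
#'   episode-end window: `variable`, `source` (`mean_shift` /
#'   `extreme_value`), `day`, `ci_lo`, `ci_hi` (= day for extremes),
#'   `direction`, `stream`, `window`.
#' @export
collect_events <- function(extremes, shifts, episode, stable,
                           streams = NULL) {
  ev <- list()
  if (!is.null(extremes) && nrow(extremes))
    ev[[1]] <- data.frame(variable = extremes$variable,
                          source = "extreme_value", day = extremes$day,
                          ci_lo = extremes$day, ci_hi = extremes$day,
                          direction = extremes$direction,
                          stringsAsFactors = FALSE)
  if (!is.null(shifts) && nrow(shifts))
    ev[[2]] <- data.frame(variable = shifts$variable,
                          source = "mean_shift", day = shifts$day,
                          ci_lo = shifts$ci_lo, ci_hi = shifts$ci_hi,
                          direction = shifts$direction,
                          stringsAsFactors = FALSE)
  ev <- do.call(rbind, ev)
  if (is.null(ev))
    ev <- data.frame(variable = character(0), source = character(0),
                     day = integer(0), ci_lo = numeric(0),
                     ci_hi = numeric(0), direction = character(0),
                     stringsAsFactors = FALSE)
  ev$stream <- vapply(ev$variable, function(v) {
    if (!is.null(streams) && v %in% names(streams)) streams[[v]]
    else if (v %in% sleep_variables()) "sleep"
    else stop("unknown variable '", v, "': not a sleep variable and not in ",
              "the streams registry", call. = FALSE)
  }, character(1), USE.NAMES = FALSE)
  ev <- ev[ev$day >= stable$start_day & ev$day <= episode$end_day, ,
           drop = FALSE]
  ev$window <- assign_window(ev$day, episode, stable)
  ev[order(ev$day), , drop = FALSE]
}

# partition of stable-start..episode-end into analysis windows
assign_window <- function(day, episode, stable) {
  out <- rep("gap", length(day))
  out[day >= stable$start_day & day <= stable$end_day] <- "stable"
  out[day >= episode$prodrome[1] & day <= episode$prodrome[2]] <- "prodrome"
  out[day >= episode$start_week_days[1] &
        day <= episode$start_week_days[2]] <- "start_week"
  out[day > episode$start_week_days[2]] <- "episode"
  out
}

#' Label per-variable changes (Table-1 logic)
#'
#' For every variable x mechanism x window, the label is `increase` /
#' `decrease` when only events of that direction occurred, `unstable` when
#' both an increase and a decrease occurred, and `none` otherwise.
#'
#' @param events output of [collect_events()].
#' @param episode an [episode_interval()].
#' @param variables variables to tabulate (rows are emitted even without
#'   events); defaults to [sleep_variables()].
#' @param windows windows to tabulate.
#' @return data.frame: `variable`, `mechanism`, `window`, `label`.
#' @export
label_changes <- function(events, episode,
                          variables = sleep_variables(),
                          windows = c("prodrome", "start_week", "stable")) {
  grid <- expand.grid(variable = variables,
                      mechanism = c("mean_shift", "extreme_value"),
                      window = windows,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$label <- mapply(function(v, m, w) {
    e <- events[events$variable == v & events$source == m &
                  events$window == w, , drop = FALSE]
    if (nrow(e) == 0L) return("none")
    inc <- any(e$direction == "increase")
    dec <- any(e$direction == "decrease")
    if (inc && dec) "unstable" else if (inc) "increase" else "decrease"
  }, grid$variable, grid$mechanism, grid$window, USE.NAMES = FALSE)
  grid
}

#' Sleep-versus-mood temporal order
#'
#' Considers events in the prodrome and start week. If either stream has no
#' events the verdict is `no_events`; if any sleep-event CI overlaps any
#' mood-event CI no order can be determined (`indeterminate`); otherwise
#' `sleep_first` when every sleep CI ends before every mood CI begins,
#' `mood_first` in the mirror case, and `indeterminate` when interleaved.
#'
#' @param events output of [collect_events()].
#' @param episode an [episode_interval()].
#' @return one of `"sleep_first"`, `"mood_first"`, `"indeterminate"`,
#'   `"no_events"`.
#' @export
temporal_order <- function(events, episode) {
  e <- events[events$window %in% c("prodrome", "start_week"), , drop = FALSE]
  s <- e[e$stream == "sleep", , drop = FALSE]
  m <- e[e$stream == "mood", , drop = FALSE]
  if (nrow(s) == 0L || nrow(m) == 0L) return("no_events")
  for (i in seq_len(nrow(s)))
    for (j in seq_len(nrow(m)))
      if (s$ci_lo[i] <= m$ci_hi[j] && m$ci_lo[j] <= s$ci_hi[i])
        return("indeterminate")
  if (max(s$ci_hi) < min(m$ci_lo)) return("sleep_first")
  if (max(m$ci_hi) < min(s$ci_lo)) return("mood_first")
  "indeterminate"
}

#' Prodromal versus stable event rates
#'
#' Events per observed day in the stable window and the prodrome, the rate
#' ratio (prodrome / stable), and an exact Poisson confidence interval for
#' the ratio (via [stats::poisson.test()]). Purely descriptive.
#'
#' @param events output of [collect_events()].
#' @param stable a `stable_period`.
#' @param episode an [episode_interval()].
#' @param observed_days optional `c(stable, prodrome)` counts of observed
#'   (non-missing) days; defaults to the full window lengths.
#' @return list with `rate_stable`, `rate_prodrome`, `rate_ratio` (NA when
#'   the stable rate is 0), `ci` and the underlying counts.
#' @export
rate_comparison <- function(events, stable, episode,
                            observed_days = c(stable$end_day -
                                                stable$start_day + 1L, 14L)) {
  if (any(observed_days == 0L))
    stop("zero observed days in a comparison window", call. = FALSE)
  n_stable <- sum(events$window == "stable")
  n_pro <- sum(events$window == "prodrome")
  rate_stable <- n_stable / observed_days[1]
  rate_pro <- n_pro / observed_days[2]
  ratio <- if (rate_stable > 0) rate_pro / rate_stable else NA_real_
  ci <- c(NA_real_, NA_real_)
  if (n_stable + n_pro > 0) {
    pt <- stats::poisson.test(c(n_pro, n_stable),
                              c(observed_days[2], observed_days[1]))
    ci <- unname(pt$conf.int)
  }
  list(rate_stable = rate_stable, rate_prodrome = rate_pro,
       rate_ratio = ratio, ci = ci,
       events_stable = n_stable, events_prodrome = n_pro,
       observed_days = observed_days)
}

#' Default analysis configuration
#'
#' @param ... overrides for any key: `sol_reference`, `min_segment`,
#'   `max_breaks`, `ci_level`, `n_boot`, `n_perm`, `supf_alpha`,
#'   `stable_strict_mode`, `missing_tolerance`, `seed`.
#' @return named list of analysis settings.
#' @export
analysis_config <- function(...) {
  cfg <- list(sol_reference = "lights_off", min_segment = 7L,
              max_breaks = 5L, ci_level = 0.95, n_boot = 500L,
              n_perm = 999L, supf_alpha = 0.05,
              stable_strict_mode = FALSE, missing_tolerance = 0.2,
              seed = 1L)
  utils::modifyList(cfg, list(...))
}

analyze_one_patient <- function(patient, cfg) {
  weekly <- patient$weekly
  lc <- patient$mood$lc_self
  episodes <- detect_episodes(weekly, lc)
  if (length(episodes) == 0L)
    return(list(excluded = TRUE, reason = "no episode detected"))
  episode <- episodes[[order(vapply(episodes, `[[`, integer(1),
                                    "start_day"))[1L]]]
  stable <- select_stable_period(weekly, lc, episode, patient$sleep,
                                 strict = cfg$stable_strict_mode)
  if (is.null(stable))
    return(list(excluded = TRUE,
                reason = "no 35-day stable period before the episode"))
  window <- c(stable$start_day, episode$end_day)
  all_series <- c(patient$sleep, patient$mood)
  streams <- stats::setNames(
    ifelse(names(all_series) %in% sleep_variables(), "sleep", "mood"),
    names(all_series))

  extremes <- list(); shifts <- list(); charts <- list()
  for (nm in names(all_series)) {
    ser <- all_series[[nm]]
    lim <- withCallingHandlers(
      compute_limits(ser, stable),
      warning = function(w) invokeRestart("muffleWarning"))
    if (!is.null(lim)) {
      extremes[[nm]] <- flag_extremes(ser, lim, window)
      charts[[nm]] <- chart_table(ser, lim, window)
    }
    shifts[[nm]] <- detect_mean_shifts(
      ser, window, min_segment = cfg$min_segment,
      max_breaks = cfg$max_breaks, level = cfg$ci_level,
      n_boot = cfg$n_boot, supf_alpha = cfg$supf_alpha,
      n_perm = cfg$n_perm)
  }
  extremes <- do.call(rbind, unname(extremes))
  shifts <- do.call(rbind, unname(shifts))
  events <- collect_events(extremes, shifts, episode, stable, streams)
  list(excluded = FALSE,
       episode = episode, stable = stable,
       charts = charts, extremes = extremes, shifts = shifts,
       events = events,
       labels = label_changes(events, episode),
       order = temporal_order(events, episode),
       rates = rate_comparison(events, stable, episode))
}

#' Run the full single-case pipeline on a cohort
#'
#' For each patient: detect episodes, select the stable period (patients
#' without one are excluded and logged), compute control charts and mean
#' shifts for all seven sleep variables and all mood items over the
#' stable-start to episode-end window, and derive change labels, the
#' temporal-order verdict and the rate comparison.
#'
#' @param cohort a `synthetic_cohort` (or any list with the same per-patient
#'   structure: `sleep`, `mood`, `weekly`).
#' @param cfg an [analysis_config()].
#' @return list of per-patient results; excluded patients carry
#'   `excluded = TRUE` and a `reason`.
#' @export
run_pipeline <- function(cohort, cfg = analysis_config()) {
  set.seed(cfg$seed)
  lapply(seq_along(cohort$patients), function(p) {
    res <- analyze_one_patient(cohort$patients[[p]], cfg)
    if (res$excluded)
      message("patient ", p, " excluded: ", res$reason)
    res$patient <- p
    res
  })
}

#' Plot one variable's single-case timeline
#'
#' A plain timeline of a daily variable with the stable period, prodrome
#' and episode bands, control limits, flagged extreme values and mean
#' shifts with their confidence intervals. Requires ggplot2.
#'
#' @param series a [daily_series()].
#' @param result one patient's entry from [run_pipeline()].
#' @return a ggplot object.
#' @export
plot_variable_timeline <- function(series, result) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  ep <- result$episode; st <- result$stable
  d <- data.frame(day = seq_len(series$study_days), value = series$values)
  ev <- result$events[result$events$variable == series$name, , drop = FALSE]
  g <- ggplot2::ggplot(d, ggplot2::aes(x = .data$day, y = .data$value)) +
    ggplot2::annotate("rect", xmin = st$start_day, xmax = st$end_day,
                      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "gold") +
    ggplot2::annotate("rect", xmin = ep$start_day, xmax = ep$end_day,
                      ymin = -Inf, ymax = Inf, alpha = 0.15,
                      fill = if (ep$polarity == "manic") "darkgreen" else "red") +
    ggplot2::geom_vline(xintercept = ep$prodrome[1], linetype = "dashed") +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::labs(title = series$name, x = "study day", y = series$name)
  ch <- result$charts[[series$name]]
  if (!is.null(ch))
    g <- g + ggplot2::geom_hline(yintercept = c(ch$ucl[1], ch$lcl[1]),
                                 linetype = "dotted")
  if (nrow(ev))
    g <- g + ggplot2::geom_point(data = data.frame(day = ev$day,
                                                   value = series$values[ev$day]),
                                 color = "red", shape = 17, size = 3,
                                 na.rm = TRUE)
  g
}
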