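# A fixed episode (start week 13 -> start day 85) and stable period for
# window-logic tests.
ep_fix <- episode_interval("depressive", 13:15)
st_fix <- structure(list(start_day = 1L, end_day = 35L, stats = NULL),
                    class = "stable_period")

mk_extreme <- function(variable, day, direction = "increase")
  data.frame(variable = variable, day = day, value = NA_real_,
             direction = direction, magnitude_sd = 3.5,
             stringsAsFactors = FALSE)

mk_shift <- function(variable, day, ci_lo, ci_hi, direction = "increase")
  data.frame(variable = variable, day = day, ci_lo = ci_lo, ci_hi = ci_hi,
             pre_mean = 0, post_mean = if (direction == "increase") 1 else -1,
             direction = direction, supF = 20, p = 0.001,
             stringsAsFactors = FALSE)

test_that("events are tagged with stream and window; boundaries are closed", {
  ev <- collect_events(mk_extreme("sleep_offset", 80),
                       mk_shift("lc_self", 86, 83, 90),
                       ep_fix, st_fix,
                       streams = c(lc_self = "mood"))
  expect_equal(ev$window[ev$variable == "sleep_offset"], "prodrome")
  expect_equal(ev$stream, c("sleep", "mood"))
  expect_equal(ev$window[ev$variable == "lc_self"], "start_week")

  # an event on the start day itself belongs to the start week, not prodrome
  ev2 <- collect_events(mk_extreme("waso", 85), NULL, ep_fix, st_fix)
  expect_equal(ev2$window, "start_week")
  # day 84 is the last prodrome day; day 70 is the gap between stable and prodrome
  expect_equal(collect_events(mk_extreme("waso", 84), NULL, ep_fix,
                              st_fix)$window, "prodrome")
  expect_equal(collect_events(mk_extreme("waso", 70), NULL, ep_fix,
                              st_fix)$window, "gap")
  # events outside stable-start..episode-end are dropped
  expect_equal(nrow(collect_events(mk_extreme("waso", 110), NULL, ep_fix,
                                   st_fix)), 0)
  expect_error(collect_events(mk_extreme("unregistered", 80), NULL, ep_fix,
                              st_fix), "unknown variable")
})

test_that("every in-window day maps to exactly one analysis window", {
  days <- st_fix$start_day:ep_fix$end_day
  w <- prodromewatch:::assign_window(days, ep_fix, st_fix)
  expect_equal(sort(unique(w)),
               c("episode", "gap", "prodrome", "stable", "start_week"))
  expect_equal(sum(w == "prodrome"), 14)
  expect_equal(sum(w == "start_week"), 7)
  expect_equal(sum(w == "stable"), 35)
  # prodrome and start week never overlap
  expect_equal(length(days), length(w))
})

test_that("change labels implement the increase/decrease/unstable/none logic", {
  ev <- collect_events(
    rbind(mk_extreme("sleep_offset", 80, "increase"),
          mk_extreme("sleep_onset", 82, "increase"),
          mk_extreme("sleep_onset", 83, "decrease")),
    mk_shift("sleep_offset", 78, 75, 83, "increase"),
    ep_fix, st_fix)
  lab <- label_changes(ev, ep_fix)
  expect_equal(nrow(lab), 7 * 2 * 3)                   # Table-1 shape
  get <- function(v, m, w)
    lab$label[lab$variable == v & lab$mechanism == m & lab$window == w]
  expect_equal(get("sleep_offset", "extreme_value", "prodrome"), "increase")
  expect_equal(get("sleep_offset", "mean_shift", "prodrome"), "increase")
  expect_equal(get("sleep_onset", "extreme_value", "prodrome"), "unstable")
  expect_equal(get("sleep_duration", "mean_shift", "prodrome"), "none")
  expect_equal(get("sleep_onset", "extreme_value", "start_week"), "none")
})

test_that("temporal order follows the CI-overlap rule", {
  sleep_ev <- function(lo, hi) {
    e <- collect_events(NULL, mk_shift("waso", lo, lo, hi), ep_fix, st_fix)
    e
  }
  mood_ev <- function(lo, hi)
    collect_events(NULL, mk_shift("lc_self", lo, lo, hi), ep_fix, st_fix,
                   streams = c(lc_self = "mood"))
  # overlap -> indeterminate
  expect_equal(temporal_order(rbind(sleep_ev(78, 82), mood_ev(80, 86)),
                              ep_fix), "indeterminate")
  # strict separation -> sleep first
  expect_equal(temporal_order(rbind(sleep_ev(72, 75), mood_ev(80, 85)),
                              ep_fix), "sleep_first")
  expect_equal(temporal_order(rbind(mood_ev(72, 75), sleep_ev(80, 85)),
                              ep_fix), "mood_first")
  # interleaved without overlap -> indeterminate
  expect_equal(temporal_order(rbind(sleep_ev(71, 72), sleep_ev(83, 84),
                                    mood_ev(76, 79)), ep_fix),
               "indeterminate")
  # one stream silent -> no_events
  expect_equal(temporal_order(sleep_ev(72, 75), ep_fix), "no_events")
})

test_that("rate comparison is events per observed day with a Poisson CI", {
  ev <- collect_events(
    rbind(mk_extreme("waso", 5), mk_extreme("waso", 12),
          mk_extreme("sol", 30), mk_extreme("sol", 74),
          mk_extreme("cpd", 80)),
    NULL, ep_fix, st_fix)
  rc <- rate_comparison(ev, st_fix, ep_fix)
  expect_equal(rc$events_stable, 3)
  expect_equal(rc$events_prodrome, 2)
  expect_equal(rc$rate_stable, 3 / 35)
  expect_equal(rc$rate_prodrome, 2 / 14)
  expect_equal(rc$rate_ratio, (2 / 14) / (3 / 35), tolerance = 1e-12)
  expect_lt(rc$ci[1], rc$rate_ratio); expect_gt(rc$ci[2], rc$rate_ratio)

  # doubling prodrome events doubles the prodrome rate
  ev2 <- collect_events(
    rbind(mk_extreme("waso", 5), mk_extreme("waso", 12),
          mk_extreme("sol", 30), mk_extreme("sol", 74),
          mk_extreme("cpd", 80), mk_extreme("cpd", 81)),
    NULL, ep_fix, st_fix)
  expect_equal(rate_comparison(ev2, st_fix, ep_fix)$rate_prodrome, 3 / 14)

  # zero events in both windows: rates 0, ratio undefined
  none <- collect_events(NULL, NULL, ep_fix, st_fix)
  rc0 <- rate_comparison(none, st_fix, ep_fix)
  expect_equal(rc0$rate_stable, 0)
  expect_true(is.na(rc0$rate_ratio))
})

test_that("pipeline recovers an injected prodromal mean shift end to end", {
  cfg <- cohort_config(1, episode_scripts = list(
    episode_script(1, "depressive", 13, 3)),           # start day 85
    injection_scripts = list(
      injection_script(1, "sleep_duration", 76, "mean_shift", -2.5)),
    seed = 2718)
  co <- generate_cohort(cfg)
  res <- run_pipeline(co, analysis_config(n_boot = 150, n_perm = 199,
                                          seed = 1))[[1]]
  expect_false(res$excluded)
  lab <- res$labels
  hit <- lab$label[lab$variable == "sleep_duration" &
                     lab$mechanism == "mean_shift" & lab$window == "prodrome"]
  expect_equal(hit, "decrease")
  expect_true(res$order %in% c("indeterminate", "sleep_first", "mood_first",
                               "no_events"))
})

test_that("patients without a feasible stable period are excluded and logged", {
  # an episode detected at week 8 leaves exactly 35 + 14 days: feasible;
  # shrink the study instead so no 35-day window precedes the episode
  cfg <- cohort_config(1, study_days = 180,
                       episode_scripts = list(episode_script(1, "manic", 8, 2)),
                       seed = 4)
  co <- generate_cohort(cfg)
  # force infeasibility: pretend the episode started at week 6
  co$patients[[1]]$weekly$asrm[1:12] <- 0
  co$patients[[1]]$weekly$asrm[6:7] <- 8
  lc <- co$patients[[1]]$mood$lc_self$values
  lc[36:49] <- 70
  co$patients[[1]]$mood$lc_self <- daily_series("lc_self", lc)
  expect_message(res <- run_pipeline(co, analysis_config(n_boot = 50,
                                                         n_perm = 99)),
                 "excluded")
  expect_true(res[[1]]$excluded)
})
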