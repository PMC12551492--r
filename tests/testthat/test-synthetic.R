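test_that("scripted episode weeks satisfy the scale thresholds by construction", {
  cfg <- cohort_config(1, episode_scripts = list(
    episode_script(1, "depressive", start_week = 13, duration_weeks = 3)),
    seed = 5)
  pat <- generate_cohort(cfg)$patients[[1]]
  expect_true(all(pat$weekly$ids_sr[13:15] > 25))
  expect_true(all(pat$weekly$ids_sr[-(13:15)] <= 25))
  expect_true(all(pat$weekly$asrm <= 5))
})

test_that("generation is deterministic given config + seed", {
  cfg <- cohort_config(2, episode_scripts = list(
    episode_script(1, "manic", 10, 2)), seed = 99)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  cfg2 <- cohort_config(2, episode_scripts = list(
    episode_script(1, "manic", 10, 2)), seed = 100)
  expect_false(identical(generate_cohort(cfg)$patients[[1]]$sleep$sol$values,
                         generate_cohort(cfg2)$patients[[1]]$sleep$sol$values))
})

test_that("scripted episodes are recovered by the detectors (self-consistency)", {
  scripts <- list(episode_script(1, "manic", 9, 2),
                  episode_script(2, "depressive", 15, 4),
                  episode_script(3, "manic", 20, 3))
  cfg <- cohort_config(3, episode_scripts = scripts, seed = 17)
  co <- generate_cohort(cfg)
  for (p in 1:3) {
    pat <- co$patients[[p]]
    eps <- detect_episodes(pat$weekly, pat$mood$lc_self)
    expect_length(eps, 1)
    expect_equal(eps[[1]]$polarity, scripts[[p]]$polarity)
    expect_equal(eps[[1]]$start_week, scripts[[p]]$start_week)
  }
})

test_that("episodes too close to day 1 are rejected with an explanation", {
  expect_error(cohort_config(1, episode_scripts = list(
    episode_script(1, "manic", 7, 2))),
    "too close to day 1")
  expect_error(episode_script(1, "depressive", 13, 2), ">= 3")
  expect_error(episode_script(1, "manic", 13, 1), ">= 2")
  expect_error(cohort_config(1, study_days = 40), ">= 49")
})

test_that("mean-shift injection moves the post-injection mean by ~magnitude SDs", {
  cfg <- cohort_config(1, episode_scripts = list(
    episode_script(1, "depressive", 14, 3)),           # start day 92
    injection_scripts = list(
      injection_script(1, "sleep_duration", 80, "mean_shift", -2)),
    seed = 11)
  pat <- generate_cohort(cfg)$patients[[1]]
  sd0 <- default_baseline_params()$sleep_duration[["sd"]]
  v <- pat$sleep$sleep_duration$values
  shift_sd <- (mean(v[80:91]) - mean(v[1:79])) / sd0
  expect_lt(abs(shift_sd - (-2)), 0.6)                 # sampling noise at n=12
})

test_that("inject_change follows its single-day / persistent contracts", {
  base <- daily_series("waso", rep(0, 70))
  # extreme value: day set to baseline mean + magnitude * SD
  inj <- inject_change(base, injection_script(1, "waso", 40, "extreme_value",
                                              3.5),
                       stable_sd = 1, baseline_mean = 0)
  expect_equal(inj$values[40], 3.5)
  expect_equal(inj$values[-40], rep(0, 69))
  expect_gt(inj$values[40], 0 + 3 * 1)                 # beyond the 3-SD limit
  # zero-magnitude mean shift is the identity
  id <- inject_change(base, injection_script(1, "waso", 40, "mean_shift", 0),
                      stable_sd = 1)
  expect_equal(id$values, base$values)
  # mean shift persists from day to end_day
  ms <- inject_change(base, injection_script(1, "waso", 40, "mean_shift", 2),
                      stable_sd = 1.5, end_day = 60)
  expect_equal(unique(ms$values[40:60]), 3)
  expect_equal(unique(ms$values[c(1:39, 61:70)]), 0)
  expect_error(injection_script(1, "not_a_var", 40, "mean_shift", 1),
               "unknown sleep variable")
})

test_that("injected mean shifts are recovered by the changepoint module", {
  set.seed(303)
  errs <- replicate(60, {
    y <- rnorm(70)
    ser <- inject_change(daily_series("sol", y),
                         injection_script(1, "sol", 40, "mean_shift", 2),
                         stable_sd = 1, baseline_mean = 0)
    segs <- segment_series(ser, min_segment = 7, max_breaks = 2)
    m <- max(select_n_breaks(segs), 1L)
    breaks <- segs[[m + 1]]$break_days + 1L            # first day of new regime
    min(abs(breaks - 40))
  })
  expect_lte(median(errs), 3)
})

test_that("null cohorts are Gaussian with ~0.27% of points beyond 3-SD limits", {
  cfg <- cohort_config(4, seed = 1234)
  co <- generate_cohort(cfg)
  n_out <- 0L; n_tot <- 0L
  for (pat in co$patients) {
    for (nm in sleep_variables()) {
      v <- pat$sleep[[nm]]$values
      lim <- compute_limits(pat$sleep[[nm]], list(start_day = 1, end_day = 35))
      fl <- flag_extremes(pat$sleep[[nm]], lim, c(36L, 180L))
      n_out <- n_out + nrow(fl)
      n_tot <- n_tot + 145L
      expect_gt(shapiro.test(v)$p.value, 1e-4)         # normality sanity check
    }
  }
  # 4 patients x 7 vars x 145 days = 4060 day-evaluations; binomial tolerance
  expect_lte(n_out / n_tot, 0.02)
})

test_that("missing-data injection hits roughly the configured daily rate", {
  cfg <- cohort_config(1, missing_rate = 0.1, seed = 8)
  pat <- generate_cohort(cfg)$patients[[1]]
  frac <- mean(vapply(pat$sleep, function(s) mean(is.na(s$values)),
                      numeric(1)))                     # 7 x 180 day draws
  expect_gt(frac, 0.06); expect_lt(frac, 0.14)
})

test_that("generated epoch nights separate rest from day and mark bouts", {
  set.seed(55)
  plain <- generate_epoch_night(c(11.5, 19.5))
  t0 <- (seq_along(plain$epochs$counts) - 1) / 60
  in_rest <- t0 >= 11.5 & t0 < 19.5
  expect_lt(mean(plain$epochs$counts[in_rest]),
            mean(plain$epochs$counts[!in_rest]))

  bouts <- list(c(14, 14 + 1 / 3), c(17, 17 + 1 / 6))
  night <- generate_epoch_night(c(11.5, 19.5), bouts, seed = 56)
  in_bout <- (t0 >= 14 & t0 < 14 + 1 / 3) | (t0 >= 17 & t0 < 17 + 1 / 6)
  expect_equal(sum(in_bout), 30)                       # 30 min elevated
  expect_gt(mean(night$epochs$counts[in_bout]), 100)
  expect_equal(night$truth$waso_min, 30)
  expect_error(generate_epoch_night(c(11.5, 19.5),
                                    list(c(14, 15), c(14.5, 15.5))),
               "overlap")
})

test_that("cohort CSV writers emit the documented plain-text layout", {
  cfg <- cohort_config(1, episode_scripts = list(
    episode_script(1, "manic", 10, 2)), seed = 3)
  co <- generate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort_csv(co, dir)
  files <- list.files(dir)
  expect_true("patient1_weekly.csv" %in% files)
  expect_true("patient1_mood.csv" %in% files)
  expect_true("patient1_truth.txt" %in% files)
  wk <- read_weekly_scales(file.path(dir, "patient1_weekly.csv"))
  expect_equal(wk, co$patients[[1]]$weekly)
  dur <- read_daily_series(file.path(dir, "patient1_sleep_sleep_duration.csv"),
                           "sleep_duration")
  expect_equal(dur$values, co$patients[[1]]$sleep$sleep_duration$values)
  expect_match(readLines(file.path(dir, "patient1_truth.txt"))[1],
               "polarity=manic start_week=10")
})
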