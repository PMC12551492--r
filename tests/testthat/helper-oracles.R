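# Independent oracles used across tests.

# Exhaustive least-squares segmentation: enumerate all placements of m
# breaks with min segment h, return the minimal-RSS configuration.
brute_force_segmentation <- function(x, m, h) {
  n <- length(x)
  rss_of <- function(bounds) {
    sum(vapply(seq_len(length(bounds) - 1L), function(s) {
      seg <- x[(bounds[s] + 1L):bounds[s + 1L]]
      sum((seg - mean(seg))^2)
    }, numeric(1)))
  }
  if (m == 0L) return(list(breaks = integer(0), rss = rss_of(c(0L, n))))
  best <- NULL
  for (ci in seq_len(ncol(cand <- utils::combn(n - 1L, m)))) {
    b <- cand[, ci]
    if (any(diff(c(0L, b, n)) < h)) next
    rss <- rss_of(c(0L, b, n))
    if (is.null(best) || rss < best$rss - 1e-10) best <- list(breaks = b, rss = rss)
  }
  best
}

# A minimal synthetic patient built directly from daily series (no RNG
# beyond what the caller seeds): quiet weekly scales with one scripted
# depressive episode and LC-self consistent with it.
quiet_patient <- function(study_days = 180L, episode_start_week = 13L,
                          episode_weeks = 3L) {
  cfg <- cohort_config(
    1, study_days = study_days,
    episode_scripts = list(episode_script(1, "depressive",
                                          episode_start_week, episode_weeks)),
    seed = 42L)
  generate_cohort(cfg)$patients[[1]]
}
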