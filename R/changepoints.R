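#' Mean-shift changepoint analysis
#'
#' Structural mean shifts in a daily series are estimated by least-squares
#' segmentation: the piecewise-constant fit with `m` breaks minimising the
#' residual sum of squares, computed by dynamic programming over break
#' positions with a minimum segment size (default 7 observed days). The
#' number of breaks is chosen by BIC (m = 0, "no change", is admissible);
#' the existence of any break is tested by a supF statistic with a
#' permutation null; and each break date receives a bootstrap confidence
#' interval from within-segment residual resampling.
#'
#' Missing days are dropped before segmentation and break indices are mapped
#' back to study days, so a break day is always an observed day.
#'
#' @name changepoints
NULL

# segment cost matrix: cost[i, j] = RSS of a constant fit to y[i..j]
segment_cost_matrix <- function(y) {
  n <- length(y)
  cs <- c(0, cumsum(y))
  cs2 <- c(0, cumsum(y^2))
  i <- rep(seq_len(n), each = n)
  j <- rep(seq_len(n), times = n)
  len <- j - i + 1L
  s <- cs[j + 1L] - cs[i]
  cost <- (cs2[j + 1L] - cs2[i]) - s^2 / len
  cost[len < 1L] <- Inf
  matrix(pmax(cost, 0), n, n, byrow = TRUE)
}

#' Least-squares segmentation of a daily series
#'
#' For each candidate break count `m = 0 .. max_breaks`, computes the
#' globally RSS-optimal piecewise-constant segmentation of the non-missing
#' values, subject to every segment containing at least `min_segment`
#' observed days. Ties are broken toward the earliest break day.
#'
#' @param y a [daily_series()] or numeric vector (NA = missing day).
#' @param min_segment minimum observed days per segment (default 7).
#' @param max_breaks largest break count to fit (default 5; reduced
#'   automatically when the series is too short for that many segments).
#' @return list of `segmentation` objects, one per feasible `m`, each with
#'   `n_breaks`, `break_days` (study day of the last observation of each
#'   left segment), `break_obs` (positions in the observed sequence),
#'   `segment_means`, `rss`, `obs_days`.
#' @export
segment_series <- function(y, min_segment = 7L, max_breaks = 5L) {
  v <- as_daily_values(y)
  obs_days <- which(!is.na(v))
  x <- v[obs_days]
  n <- length(x)
  h <- as.integer(min_segment)
  if (n < 2L * h)
    stop("series too short for segmentation: ", n, " observed days; ",
         "at least ", 2L * h, " required (min_segment = ", h, ")",
         call. = FALSE)
  max_m <- min(as.integer(max_breaks), n %/% h - 1L)
  cost <- segment_cost_matrix(x)

  # D[m+1, j]: minimal RSS of fitting x[1..j] with m breaks; A: argmin split
  D <- matrix(Inf, max_m + 1L, n)
  A <- matrix(NA_integer_, max_m + 1L, n)
  D[1L, h:n] <- cost[1L, h:n]
  if (max_m >= 1L) {
    for (m in seq_len(max_m)) {
      for (j in seq.int((m + 1L) * h, n)) {
        k <- seq.int(m * h, j - h)       # last obs of segment m
        tot <- D[m, k] + cost[k + 1L, j]
        best <- which.min(tot)           # first minimum = earliest break
        D[m + 1L, j] <- tot[best]
        A[m + 1L, j] <- k[best]
      }
    }
  }

  lapply(0:max_m, function(m) {
    breaks <- integer(0)
    j <- n
    mm <- m
    while (mm >= 1L) {
      k <- A[mm + 1L, j]
      breaks <- c(k, breaks)
      j <- k
      mm <- mm - 1L
    }
    bounds <- c(0L, breaks, n)
    means <- vapply(seq_len(m + 1L), function(s)
      mean(x[(bounds[s] + 1L):bounds[s + 1L]]), numeric(1))
    structure(list(n_breaks = m,
                   break_obs = breaks,
                   break_days = obs_days[breaks],
                   segment_means = means,
                   rss = unname(D[m + 1L, n]),
                   obs_days = obs_days,
                   min_segment = h),
              class = "segmentation")
  })
}

#' @export
print.segmentation <- function(x, ...) {
  cat("<segmentation> m=", x$n_breaks, ", rss=", signif(x$rss, 5),
      if (x$n_breaks) paste0(", break days ",
                             paste(x$break_days, collapse = ", ")),
      "\n", sep = "")
  invisible(x)
}

#' Choose the number of breaks by BIC
#'
#' BIC(m) = n log(rss/n) + p log(n) with p = (m+1) segment means + m break
#' positions + 1 variance = 2m + 2. A zero-RSS fit gets BIC -Inf; the
#' smallest such m wins.
#'
#' @param segmentations output of [segment_series()].
#' @param criterion only `"BIC"` currently.
#' @return the chosen break count `m` (possibly 0).
#' @export
select_n_breaks <- function(segmentations, criterion = "BIC") {
  criterion <- match.arg(criterion, "BIC")
  n <- length(segmentations[[1]]$obs_days)
  bic <- vapply(segmentations, function(s) {
    m <- s$n_breaks
    if (s$rss <= 0) return(-Inf)
    n * log(s$rss / n) + (2 * m + 2) * log(n)
  }, numeric(1))
  segmentations[[which.min(bic)]]$n_breaks
}

# RSS profile over all admissible single splits of y (vectorized);
# returns list(k = candidate last-left indices, rss = two-segment RSS)
single_break_profile <- function(y, h) {
  n <- length(y)
  k <- seq.int(h, n - h)
  cs <- cumsum(y); cs2 <- cumsum(y^2)
  rss_l <- cs2[k] - cs[k]^2 / k
  s_r <- cs[n] - cs[k]; s2_r <- cs2[n] - cs2[k]
  rss_r <- s2_r - s_r^2 / (n - k)
  list(k = k, rss = pmax(rss_l, 0) + pmax(rss_r, 0))
}

#' supF test for the existence of a mean shift
#'
#' The statistic is the maximum over admissible single-break positions of
#' the F statistic comparing the one-mean fit against the two-mean fit.
#' Its null distribution is obtained by permuting the observed values
#' (exchangeability under a constant mean) and recomputing the statistic.
#'
#' @param y a [daily_series()] or numeric vector.
#' @param min_segment minimum observed days on each side of a candidate
#'   break.
#' @param n_perm permutation replicates (>= 999 recommended).
#' @return list with `statistic` (supF) and `p_value` =
#'   (1 + #\{permuted supF >= observed\}) / (n_perm + 1). Reproducible given
#'   the RNG seed in effect at the call.
#' @export
sup_f_test <- function(y, min_segment = 7L, n_perm = 999L) {
  v <- as_daily_values(y)
  x <- v[!is.na(v)]
  n <- length(x)
  h <- as.integer(min_segment)
  if (n < 2L * h)
    stop("series too short for supF test: need >= ", 2L * h,
         " observed days", call. = FALSE)
  supf <- function(z) {
    rss0 <- sum((z - mean(z))^2)
    if (rss0 < .Machine$double.eps * n) return(0)
    prof <- single_break_profile(z, h)
    rss1 <- min(prof$rss)
    if (rss1 < .Machine$double.eps * n) return(Inf)
    (rss0 - rss1) / (rss1 / (n - 2))
  }
  obs <- supf(x)
  perm <- vapply(seq_len(n_perm), function(i) supf(sample(x)), numeric(1))
  list(statistic = obs,
       p_value = (1 + sum(perm >= obs)) / (n_perm + 1))
}

#' Bootstrap confidence intervals for break dates
#'
#' For each break, the two flanking segments are rebuilt from their fitted
#' means plus residuals resampled i.i.d. (pooled across the two segments),
#' the single break is re-estimated inside that flanking region, and the
#' interval is the level-quantile range of re-estimated break days, clipped
#' to the flanking segments and widened (if needed) to contain the point
#' estimate. The break day reported here is the first day of the new
#' regime.
#'
#' @param y a [daily_series()] or numeric vector (same one that was
#'   segmented).
#' @param segmentation a `segmentation` with `n_breaks >= 1`.
#' @param level confidence level (default 0.95).
#' @param n_boot bootstrap replicates (default 500).
#' @return data.frame with one row per break: `day` (first day of the new
#'   regime), `ci_lo`, `ci_hi`, `pre_mean`, `post_mean`, `direction`.
#' @export
breakpoint_ci <- function(y, segmentation, level = 0.95, n_boot = 500L) {
  v <- as_daily_values(y)
  obs_days <- segmentation$obs_days
  x <- v[obs_days]
  h <- segmentation$min_segment
  m <- segmentation$n_breaks
  stopifnot(m >= 1L)
  bounds <- c(0L, segmentation$break_obs, length(x))
  out <- vector("list", m)
  for (b in seq_len(m)) {
    lo <- bounds[b] + 1L; mid <- bounds[b + 1L]; hi <- bounds[b + 2L]
    region <- lo:hi
    z <- x[region]
    fit <- c(rep(segmentation$segment_means[b], mid - lo + 1L),
             rep(segmentation$segment_means[b + 1L], hi - mid))
    res <- z - fit
    day <- obs_days[mid + 1L]            # first obs of the new regime
    boot_days <- vapply(seq_len(n_boot), function(i) {
      zb <- fit + sample(res, length(res), replace = TRUE)
      prof <- single_break_profile(zb, h)
      k <- prof$k[which.min(prof$rss)]   # region-local last-left index
      obs_days[region[k] + 1L]           # first day of new regime
    }, numeric(1))
    boot_days <- boot_days[!is.na(boot_days)]
    if (length(boot_days) < 2L) {
      message("breakpoint CI degenerate for break at day ", day,
              ": too few valid bootstrap re-estimates")
      ci <- c(day, day)
    } else {
      a <- (1 - level) / 2
      ci <- unname(stats::quantile(boot_days, c(a, 1 - a), type = 1))
    }
    ci <- c(max(ci[1], obs_days[lo]), min(ci[2], obs_days[hi]))
    ci <- c(min(ci[1], day), max(ci[2], day))  # CI always contains the break
    out[[b]] <- data.frame(
      day = day, ci_lo = ci[1], ci_hi = ci[2],
      pre_mean = segmentation$segment_means[b],
      post_mean = segmentation$segment_means[b + 1L],
      direction = if (segmentation$segment_means[b + 1L] >
                      segmentation$segment_means[b]) "increase" else "decrease",
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Full mean-shift analysis of one series
#'
#' Convenience wrapper: segments the series within a day window, picks the
#' break count by BIC, gates on the supF test (p < `supf_alpha`; no breaks
#' are reported when the gate fails or BIC picks m = 0), and attaches
#' bootstrap CIs.
#'
#' @param series a [daily_series()].
#' @param window day interval `c(from, to)` to analyse (typically stable
#'   start to episode end).
#' @param min_segment,max_breaks see [segment_series()].
#' @param level,n_boot see [breakpoint_ci()].
#' @param supf_alpha significance level of the supF gate; `NULL` disables
#'   the gate.
#' @param n_perm permutation replicates for the supF test.
#' @return data.frame of mean shifts (possibly zero rows): `variable`,
#'   `day`, `ci_lo`, `ci_hi`, `pre_mean`, `post_mean`, `direction`, `supF`,
#'   `p`.
#' @export
detect_mean_shifts <- function(series, window = c(1L, series$study_days),
                               min_segment = 7L, max_breaks = 5L,
                               level = 0.95, n_boot = 500L,
                               supf_alpha = 0.05, n_perm = 999L) {
  v <- as_daily_values(series)
  sub <- rep(NA_real_, length(v))
  sub[window[1]:window[2]] <- v[window[1]:window[2]]
  empty <- data.frame(variable = character(0), day = integer(0),
                      ci_lo = numeric(0), ci_hi = numeric(0),
                      pre_mean = numeric(0), post_mean = numeric(0),
                      direction = character(0), supF = numeric(0),
                      p = numeric(0), stringsAsFactors = FALSE)
  if (sum(!is.na(sub)) < 2L * min_segment) return(empty)
  segs <- segment_series(sub, min_segment, max_breaks)
  ft <- sup_f_test(sub, min_segment, n_perm)
  if (!is.null(supf_alpha) && !(ft$p_value < supf_alpha)) return(empty)
  m <- select_n_breaks(segs)
  if (m == 0L) return(empty)
  ci <- breakpoint_ci(sub, segs[[m + 1L]], level, n_boot)
  cbind(data.frame(variable = series$name, stringsAsFactors = FALSE),
        ci, supF = ft$statistic, p = ft$p_value)
}
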