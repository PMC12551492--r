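#' Clock-time and timeline conversions
#'
#' All night times in this package live on a continuous "noon-anchored"
#' timeline: hours elapsed since the noon preceding the night. Midnight is
#' 12, 23:30 is 11.5, 07:30 (next morning) is 19.5. Nights that cross
#' midnight are therefore monotone and differences are plain subtraction,
#' with no mod-24 wraparound. The calendar date of a night is the date of
#' the morning on which it ends.
#'
#' @param x clock time as `"HH:MM"` / `"HH:MM:SS"` character, or numeric
#'   hour-of-day in `[0, 24)`.
#' @return hours since the preceding noon, in `[0, 24)`.
#' @examples
#' clock_to_timeline("23:30") # 11.5
#' clock_to_timeline("07:30") # 19.5
#' @export
clock_to_timeline <- function(x) {
  h <- clock_to_hours(x)
  (h - 12) %% 24
}

#' @rdname clock_to_timeline
#' @export
timeline_to_clock <- function(x) {
  h <- (x + 12) %% 24
  sprintf("%02d:%02d", floor(h), round((h - floor(h)) * 60) %% 60)
}

# "HH:MM[:SS]" or numeric hour-of-day -> numeric hour-of-day
clock_to_hours <- function(x) {
  if (is.numeric(x)) return(x %% 24)
  parts <- strsplit(as.character(x), ":", fixed = TRUE)
  vapply(parts, function(p) {
    p <- as.numeric(p)
    if (any(is.na(p)) || length(p) < 2L || length(p) > 3L)
      stop("clock time must be \"HH:MM\" or \"HH:MM:SS\"", call. = FALSE)
    (p[1] + p[2] / 60 + if (length(p) == 3L) p[3] / 3600 else 0) %% 24
  }, numeric(1))
}
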