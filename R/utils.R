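# Grid conventions: 96 samples/day, anchored at local midnight, half-open
# days [00:00, 24:00). Timestamps are site-local clock time stored as UTC
# POSIXct so no DST shift can occur inside an analysis window.

GRID_STEP_SEC <- 900L
SAMPLES_PER_DAY <- 96L

#' Regular 15-minute timestamp grid over an analysis window
#'
#' @param start_date,end_date first and last calendar day of the window
#'   (inclusive), as `Date` or anything `as.Date()` accepts.
#' @return `POSIXct` vector (UTC-stored local clock time), 96 samples per day.
#' @export
band_grid <- function(start_date, end_date) {
  start <- as.POSIXct(paste(as.Date(start_date), "00:00:00"), tz = "UTC")
  end <- as.POSIXct(paste(as.Date(end_date), "00:00:00"), tz = "UTC") + 86400
  seq(start, end - GRID_STEP_SEC, by = GRID_STEP_SEC)
}

grid_dates <- function(time) as.Date(time, tz = "UTC")

time_of_day_bin <- function(time) {
  lt <- as.POSIXlt(time, tz = "UTC")
  as.integer((lt$hour * 60L + lt$min) %/% 15L)
}

#' Snap timestamps to the nearest grid sample
#'
#' Logger clocks jitter by a few seconds to minutes; samples are snapped to
#' the nearest grid point within +/- 7.5 min. Outside that, or outside the
#' grid, the index is NA.
#'
#' @param time timestamps to snap.
#' @param grid regular 15-minute grid from [band_grid()].
#' @return integer index into `grid` (NA where unplaceable).
#' @export
snap_to_grid <- function(time, grid) {
  off <- as.numeric(time) - as.numeric(grid[1])
  idx <- as.integer(round(off / GRID_STEP_SEC)) + 1L
  bad <- idx < 1L | idx > length(grid) |
    abs(off - (idx - 1L) * GRID_STEP_SEC) > GRID_STEP_SEC / 2
  idx[bad] <- NA_integer_
  idx
}

# centered rolling MAD (raw median absolute deviation about the window
# median, no consistency constant); width must be odd
roll_mad <- function(x, width) {
  n <- length(x)
  h <- width %/% 2L
  vapply(seq_len(n), function(i) {
    w <- x[max(1L, i - h):min(n, i + h)]
    median(abs(w - median(w)))
  }, numeric(1))
}

# centered boxcar mean with partial (renormalized) edge windows, via cumsum
boxcar_mean <- function(x, width) {
  if (width <= 1L) return(x)
  h <- width %/% 2L
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# deterministic 31-bit substream seed from a parent seed and a string id
derive_seed <- function(seed, id) {
  hash <- 0
  for (ch in utf8ToInt(id)) hash <- (hash * 131 + ch) %% 2147483563
  as.integer((as.numeric(seed) * 48271 + hash) %% 2147483563 + 1)
}

`%na0%` <- function(x, y) ifelse(is.na(x), y, x)
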