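# Three-stage quality screening of band records, applied in fixed order:
# manual-check discrepancy -> jump days -> isolated spikes. Masks only ever
# grow; each screen is idempotent on its own output.

sensor_position_at <- function(band, t, max_gap_samples = 4L) {
  idx <- snap_to_grid(t, band$time)
  if (is.na(idx)) return(NA_real_)
  valid <- !band$masked & !is.na(band$position)
  for (k in 0:max_gap_samples) {
    for (i in c(idx - k, idx + k)) {
      if (i >= 1 && i <= length(band$time) && valid[i]) return(band$position[i])
    }
  }
  NA_real_
}

#' Screen against manual caliper checks
#'
#' For each pair of consecutive manual visits, the change in sensor position
#' is compared with the change in the caliper-measured window width; if the
#' two disagree by more than `tol` (default 4 mm), every sample in the
#' closed interval between the two visits is masked. Sites without repeated
#' manual measurements skip this screen (`skip = TRUE`).
#'
#' @param band a [band_series()].
#' @param checks manual check table ([read_manual_checks()]).
#' @param tol discrepancy tolerance (mm).
#' @param skip if TRUE the series is returned unchanged.
#' @return the band with its mask possibly grown.
#' @export
screen_manual_discrepancy <- function(band, checks, tol = 4, skip = FALSE) {
  if (skip) return(band)
  ck <- checks[checks$tree_id == band$tree_id, , drop = FALSE]
  ck <- ck[order(ck$visit_time), , drop = FALSE]
  if (nrow(ck) < 2) {
    warning(sprintf("tree %s: <2 manual checks, discrepancy screen skipped",
                    band$tree_id))
    return(band)
  }
  for (i in seq_len(nrow(ck) - 1)) {
    t1 <- ck$visit_time[i]; t2 <- ck$visit_time[i + 1]
    s1 <- sensor_position_at(band, t1); s2 <- sensor_position_at(band, t2)
    if (is.na(s1) || is.na(s2)) {
      warning(sprintf("tree %s: no sensor data near a manual check, pair skipped",
                      band$tree_id))
      next
    }
    d_sensor <- s2 - s1
    d_window <- ck$window_width[i + 1] - ck$window_width[i]
    if (abs(d_sensor - d_window) > tol) {
      band$masked[band$time >= t1 & band$time <= t2] <- TRUE
    }
  }
  band
}

#' Screen whole days containing sensor jumps
#'
#' Any calendar day in which some 1-hour window (5 consecutive grid
#' samples, all within the day) spans more than `threshold` mm of sensor
#' position is masked entirely.
#'
#' @param band a [band_series()].
#' @param threshold position range triggering removal (mm); per-site
#'   (default 0.5, tropical-site style 1.0).
#' @return the band with whole days possibly masked.
#' @export
screen_jump_days <- function(band, threshold = 0.5) {
  p <- band$position
  p[band$masked] <- NA_real_
  n <- length(p)
  if (n < 5) return(band)
  d <- grid_dates(band$time)
  idx <- seq_len(n - 4L)
  M <- vapply(0:4, function(k) p[idx + k], numeric(length(idx)))
  cnt <- rowSums(!is.na(M))
  suppressWarnings({
    rmax <- apply(M, 1, max, na.rm = TRUE)
    rmin <- apply(M, 1, min, na.rm = TRUE)
  })
  rng <- rmax - rmin
  same_day <- d[idx] == d[idx + 4L]
  bad <- same_day & cnt >= 2 & is.finite(rng) & rng > threshold
  if (any(bad)) {
    band$masked[d %in% unique(d[idx][bad])] <- TRUE
  }
  band
}

#' Screen isolated spikes
#'
#' Deterministic automated surrogate for visual screening of unrealistic
#' isolated records: a sample is masked when its absolute deviation from the
#' centered rolling median exceeds `k` times the rolling MAD (floored at
#' `mad_floor`) while neither neighbor does. Persistent level shifts are
#' left to the jump screen.
#'
#' @param band a [band_series()].
#' @param window rolling window length in samples (odd).
#' @param k MAD multiplier.
#' @param mad_floor lower bound on the MAD (mm) so flat records do not flag
#'   measurement-resolution noise.
#' @return the band with isolated spikes masked.
#' @export
screen_spikes <- function(band, window = 5L, k = 5, mad_floor = 0.01) {
  valid <- which(!band$masked & !is.na(band$position))
  if (length(valid) < window) return(band)
  v <- band$position[valid]
  med <- runmed(v, window, endrule = "median")
  dev <- abs(v - med)
  rmad <- roll_mad(v, window)
  flag <- dev > k * pmax(rmad, mad_floor)
  isolated <- flag &
    !c(FALSE, flag[-length(flag)]) &
    !c(flag[-1], FALSE)
  band$masked[valid[isolated]] <- TRUE
  band
}

#' Run the full screening sequence on one tree
#'
#' Applies the manual-discrepancy, jump-day and spike screens in order and
#' reports per-rule removal counts and the usable fraction (denominator:
#' all grid samples in the analysis window).
#'
#' @param band a [band_series()].
#' @param checks manual check table.
#' @param manual_tol,skip_manual see [screen_manual_discrepancy()].
#' @param jump_threshold see [screen_jump_days()].
#' @param spike_window,spike_k,mad_floor see [screen_spikes()].
#' @param min_usable usable-fraction cut for tree retention.
#' @return list with the screened `band` and a one-row `report` tibble.
#' @export
qc_tree <- function(band, checks = NULL, manual_tol = 4, skip_manual = FALSE,
                    jump_threshold = 0.5, spike_window = 5L, spike_k = 5,
                    mad_floor = 0.01, min_usable = 0.5) {
  n_total <- length(band$time)
  m0 <- band$masked
  band <- if (is.null(checks) || skip_manual) band else
    screen_manual_discrepancy(band, checks, tol = manual_tol)
  n_manual <- sum(band$masked & !m0)
  m1 <- band$masked
  band <- screen_jump_days(band, threshold = jump_threshold)
  n_jump <- sum(band$masked & !m1)
  m2 <- band$masked
  band <- screen_spikes(band, window = spike_window, k = spike_k,
                        mad_floor = mad_floor)
  n_spike <- sum(band$masked & !m2)
  frac <- usable_fraction(band)
  report <- tibble::tibble(
    tree_id = band$tree_id, n_total = n_total,
    n_gap = sum(is.na(band$position) & !band$masked),
    n_manual_discrepancy = n_manual, n_jump_day = n_jump, n_spike = n_spike,
    fraction_usable = frac, usable = frac >= min_usable)
  list(band = band, report = report)
}

#' Trees retained by the usable-data rule
#'
#' Trees with less than `min_usable` of grid samples remaining after
#' screening are excluded (strictly-less-than rule: exactly 50% is kept).
#'
#' @param reports row-bound report tibbles from [qc_tree()].
#' @param min_usable retention cut on `fraction_usable`.
#' @return character vector of retained tree ids.
#' @export
select_usable_trees <- function(reports, min_usable = 0.5) {
  reports$tree_id[reports$fraction_usable >= min_usable]
}
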