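# Phase extraction at the 1-day scale, circular statistics, and the
# shrink/swell classification of days and trees.

#' Per-sample coherence and phase at the 1-day scale
#'
#' Selects the single scale whose Fourier period is nearest 24 h, drops
#' samples inside the cone of influence (edge distance <= sqrt(2) * scale),
#' and restricts to rain-free days. Days listed in `exclude_dates` (e.g.
#' days with >= 25% gap-filled samples) are also dropped.
#'
#' @param coh a [wavelet_coherence_phase()] result.
#' @param time grid timestamps matching the coherence field.
#' @param rain_dates `Date` vector of rainy days to exclude.
#' @param exclude_dates additional `Date`s to drop.
#' @return tibble `time`, `date`, `coherence`, `phase` (phase mapped to
#'   \[0, 2 pi)).
#' @export
day_scale_series <- function(coh, time, rain_dates = NULL,
                             exclude_dates = NULL) {
  j <- which.min(abs(coh$periods - 1))
  s <- coh$scales[j]
  keep <- coh$coi > sqrt(2) * s
  dates <- grid_dates(time)
  if (!is.null(rain_dates)) keep <- keep & !(dates %in% rain_dates)
  if (!is.null(exclude_dates)) keep <- keep & !(dates %in% exclude_dates)
  if (!any(keep)) warning("day_scale_series: no qualifying samples (all rainy or inside COI)")
  tibble::tibble(time = time[keep], date = dates[keep],
                 coherence = coh$coherence[j, keep],
                 phase = coh$phase[j, keep] %% (2 * pi))
}

#' Circular mean of phase angles
#'
#' theta = atan2(sum sin, sum cos) mapped to \[0, 2 pi); the mean resultant
#' length is returned alongside. Antipodal (zero-resultant) inputs have no
#' defined mean and raise an error.
#'
#' @param angles radians.
#' @return list `theta` (\[0, 2 pi)), `r` (mean resultant length), `n`.
#' @export
circular_mean <- function(angles) {
  angles <- angles[!is.na(angles)]
  if (!length(angles)) stop("circular_mean: no angles")
  s <- sum(sin(angles)); c <- sum(cos(angles))
  r <- sqrt(s^2 + c^2) / length(angles)
  if (r < 1e-9) stop("circular_mean: zero resultant, mean undefined")
  list(theta = atan2(s, c) %% (2 * pi), r = r, n = length(angles))
}

is_shrink_angle <- function(theta) theta > pi / 2 & theta < 3 * pi / 2

#' Classify a tree's diurnal pattern from its day-scale phase series
#'
#' Tree-level mean phase angle theta uses all samples with coherence above
#' `coherence_cut` (pooled across days). A day gets theta_day (circular mean
#' of its phases) only when every retained sample that day exceeds the cut;
#' such days are classed shrink if pi/2 < theta_day < 3 pi/2 (band
#' temperature and residuals out of phase, i.e. daytime shrinkage), else
#' swell. The tree is "shrinking"/"swelling" when more than `dominance` of
#' its classified days agree, otherwise "no_dominant_pattern" (which also
#' covers trees with zero classified days; `n_classified_days` disambiguates).
#'
#' @param day_tbl tibble from [day_scale_series()].
#' @param tree_id identifier carried into the result.
#' @param coherence_cut coherence gate (default 0.7).
#' @param dominance day-fraction needed for a dominant pattern (default 0.75).
#' @return object of class `phase_result`: `theta_mean`, `r`,
#'   `n_qualifying`, per-day tibble `days` (`date`, `n_samples`,
#'   `min_coherence`, `mean_coherence`, `theta_day`, `day_class`),
#'   `tree_class`, `n_classified_days`, `frac_days_coherent`.
#' @export
classify_tree_pattern <- function(day_tbl, tree_id = NA_character_,
                                  coherence_cut = 0.7, dominance = 0.75) {
  qual <- day_tbl$coherence > coherence_cut
  theta_mean <- NA_real_; r <- NA_real_
  if (any(qual)) {
    cm <- circular_mean(day_tbl$phase[qual])
    theta_mean <- cm$theta; r <- cm$r
  }
  days <- dplyr::summarise(
    dplyr::group_by(day_tbl, .data$date),
    n_samples = dplyr::n(),
    min_coherence = min(.data$coherence),
    mean_coherence = mean(.data$coherence),
    theta_day = if (min(.data$coherence) > coherence_cut) {
      circular_mean(.data$phase)$theta
    } else NA_real_,
    .groups = "drop")
  days$day_class <- ifelse(is.na(days$theta_day), NA_character_,
                           ifelse(is_shrink_angle(days$theta_day),
                                  "shrink", "swell"))
  classified <- !is.na(days$day_class)
  n_classified <- sum(classified)
  # a tree with no qualifying (coherent) days has, literally, no dominant
  # pattern; n_classified_days = 0 keeps the distinction visible
  tree_class <- "no_dominant_pattern"
  if (n_classified > 0) {
    f_shrink <- mean(days$day_class[classified] == "shrink")
    f_swell <- mean(days$day_class[classified] == "swell")
    tree_class <- if (f_shrink > dominance) "shrinking"
      else if (f_swell > dominance) "swelling"
      else "no_dominant_pattern"
  }
  structure(list(tree_id = tree_id, theta_mean = theta_mean, r = r,
                 n_qualifying = sum(qual), days = days,
                 tree_class = tree_class, n_classified_days = n_classified,
                 frac_days_coherent = if (nrow(days)) n_classified / nrow(days)
                                      else NA_real_),
            class = "phase_result")
}

#' @export
print.phase_result <- function(x, ...) {
  cat(sprintf("<phase_result> tree %s: theta %.2f rad (r %.2f), class %s, %d/%d days coherent\n",
              x$tree_id, x$theta_mean, x$r, x$tree_class %na0% "undefined",
              x$n_classified_days, nrow(x$days)))
  invisible(x)
}

#' Day-scale phase classification for one tree against ensemble temperature
#'
#' Convenience wrapper: gap-fills the residual series, computes coherence
#' with the (already gap-free) ensemble band temperature, extracts the
#' 1-day-scale series on rain-free days outside the COI, excludes days with
#' more than `max_gap_fraction` gap-filled samples, and classifies.
#'
#' @param decomp a [decompose_tree()] result.
#' @param tband_field precomputed [morlet_cwt()] field of the ensemble band
#'   temperature on the same grid.
#' @param rain_dates rainy `Date`s to exclude.
#' @param coherence_cut,dominance see [classify_tree_pattern()].
#' @param max_gap_fraction days with more gap-filled samples are excluded
#'   from classification (default 0.25).
#' @param dj,period_range,omega0,octaves wavelet parameters.
#' @return a `phase_result`.
#' @export
phase_classify_tree <- function(decomp, tband_field, rain_dates = NULL,
                                coherence_cut = 0.7, dominance = 0.75,
                                max_gap_fraction = 0.25, dj = 1 / 20,
                                period_range = c(0.25, 4), omega0 = 6,
                                octaves = 0.6) {
  dcr <- decomp$samples$delta_c_r
  gap_by_day <- tapply(is.na(dcr), decomp$samples$date, mean)
  gappy <- as.Date(names(gap_by_day))[gap_by_day > max_gap_fraction]
  y <- gap_fill_linear(dcr)
  coh <- wavelet_coherence_phase(y = y, xfield = tband_field,
                                 dt = 1 / SAMPLES_PER_DAY, dj = dj,
                                 period_range = period_range, omega0 = omega0,
                                 octaves = octaves)
  ds <- day_scale_series(coh, decomp$samples$time, rain_dates = rain_dates,
                         exclude_dates = gappy)
  classify_tree_pattern(ds, tree_id = decomp$tree_id,
                        coherence_cut = coherence_cut, dominance = dominance)
}
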