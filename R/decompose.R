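# Decomposition of circumference change into a smoothing-spline trend,
# daily increments I (midnight-to-midnight trend differences), diurnal
# residuals delta_c_r, and daily amplitudes A = max - min of the residuals.

#' Circumference change relative to the first usable sample
#'
#' @param band a screened [band_series()].
#' @return numeric vector on the grid: position minus position at the first
#'   unmasked sample; masked samples and gaps stay NA.
#' @export
compute_delta_c <- function(band) {
  valid <- !band$masked & !is.na(band$position)
  if (!any(valid)) stop(sprintf("tree %s: no usable data", band$tree_id))
  origin <- band$position[which(valid)[1]]
  out <- band$position - origin
  out[!valid] <- NA_real_
  out
}

#' Fit the smoothing-spline trend with df equal to the number of days
#'
#' A cubic smoothing spline is fitted to the observed (unmasked) samples
#' with effective degrees of freedom (trace of the smoother matrix) equal to
#' the number of calendar days in the window; the smoothing parameter is
#' found by the monotone df-matching search in [stats::smooth.spline()] and
#' the achieved trace is verified to +/- 0.5. The spline bridges gaps and is
#' evaluated on the grid and at every midnight in the window.
#'
#' @param time grid timestamps.
#' @param delta_c circumference change from [compute_delta_c()].
#' @param n_days target df; defaults to the number of calendar days spanned
#'   by the grid.
#' @return list with `trend` (on the grid), `midnights` (tibble: `date`,
#'   `value` for midnights 0..n_days), `edf`, `lambda`.
#' @export
fit_spline_trend <- function(time, delta_c, n_days = NULL) {
  dates <- grid_dates(time)
  n_days <- n_days %||% length(unique(dates))
  obs <- !is.na(delta_c)
  if (sum(obs) < 2 * n_days) {
    stop(sprintf("insufficient data for spline: %d observed samples for df=%d",
                 sum(obs), n_days))
  }
  day0 <- as.POSIXct(paste(min(dates), "00:00:00"), tz = "UTC")
  x <- as.numeric(time - day0, units = "days")
  if (n_days > length(unique(x[obs]))) {
    stop("df request exceeds the number of distinct observed samples")
  }
  fit <- smooth.spline(x[obs], delta_c[obs], df = n_days, cv = FALSE)
  if (abs(fit$df - n_days) > 0.5) {
    fit <- smooth.spline(x[obs], delta_c[obs], df = n_days, cv = FALSE,
                         all.knots = TRUE)
    if (abs(fit$df - n_days) > 0.5) {
      stop(sprintf("df search not bracketed: target %d, achieved %.2f (lambda %.3g)",
                   n_days, fit$df, fit$lambda))
    }
  }
  xm <- 0:n_days
  list(trend = predict(fit, x)$y,
       midnights = tibble::tibble(date = min(dates) + xm,
                                  value = predict(fit, xm)$y),
       edf = fit$df, lambda = fit$lambda)
}

#' Daily circumference increment from spline midnight values
#'
#' `I_i` = spline at midnight of day i+1 minus spline at midnight of day i.
#'
#' @param midnights tibble from [fit_spline_trend()] (`date`, `value`).
#' @return tibble `date`, `I` (mm/day), one row per day with both midnights.
#' @export
daily_increment <- function(midnights) {
  n <- nrow(midnights)
  if (n < 2) stop("daily_increment: need at least two midnights")
  tibble::tibble(date = midnights$date[-n], I = diff(midnights$value))
}

#' Diurnal residuals and daily amplitude
#'
#' Residuals are delta_c minus the trend at observed samples only (gaps are
#' not bridged here). The daily amplitude A is max - min of the residuals
#' within each calendar day having at least `min_coverage` of its 96
#' samples observed; other days are gaps.
#'
#' @param delta_c,trend series on the grid.
#' @param time grid timestamps.
#' @param min_coverage minimum fraction of a day's samples required for A.
#' @return list with `delta_c_r` (on the grid) and `daily` (tibble: `date`,
#'   `n_obs`, `A`).
#' @export
residual_amplitude <- function(delta_c, trend, time, min_coverage = 0.75) {
  dcr <- delta_c - trend
  dates <- grid_dates(time)
  daily <- lapply(split(dcr, dates), function(v) {
    n_obs <- sum(!is.na(v))
    A <- if (n_obs >= min_coverage * SAMPLES_PER_DAY) {
      max(v, na.rm = TRUE) - min(v, na.rm = TRUE)
    } else NA_real_
    c(n_obs = n_obs, A = A)
  })
  list(delta_c_r = dcr,
       daily = tibble::tibble(
         date = as.Date(names(daily)),
         n_obs = unname(vapply(daily, `[[`, numeric(1), "n_obs")),
         A = unname(vapply(daily, `[[`, numeric(1), "A"))))
}

#' Full decomposition for one tree
#'
#' @param band a screened [band_series()].
#' @param n_days spline df (default: days in window).
#' @param min_coverage see [residual_amplitude()].
#' @return object of class `decomposition`: `tree_id`, `samples` tibble
#'   (`time`, `date`, `delta_c`, `trend`, `delta_c_r`), `daily` tibble
#'   (`date`, `I`, `A`, `n_obs`), `edf`.
#' @export
decompose_tree <- function(band, n_days = NULL, min_coverage = 0.75) {
  dc <- compute_delta_c(band)
  sp <- fit_spline_trend(band$time, dc, n_days = n_days)
  inc <- daily_increment(sp$midnights)
  ra <- residual_amplitude(dc, sp$trend, band$time, min_coverage = min_coverage)
  daily <- dplyr::left_join(inc, ra$daily, by = "date")
  structure(list(
    tree_id = band$tree_id,
    samples = tibble::tibble(time = band$time, date = grid_dates(band$time),
                             delta_c = dc, trend = sp$trend,
                             delta_c_r = ra$delta_c_r),
    daily = daily, edf = sp$edf), class = "decomposition")
}

#' @export
print.decomposition <- function(x, ...) {
  cat(sprintf("<decomposition> tree %s: %d days, edf %.2f, mean I %.4f mm/day, mean A %.3f mm\n",
              x$tree_id, nrow(x$daily), x$edf,
              mean(x$daily$I, na.rm = TRUE), mean(x$daily$A, na.rm = TRUE)))
  invisible(x)
}

#' Site ensemble band temperature
#'
#' Pools temperature records by time-of-day bin (96 bins) across trees and
#' days; within each bin, values outside 1.5 IQR beyond the quartiles
#' (linear-interpolation quartiles) are flagged as outliers unless the bin
#' holds fewer than 4 values. The ensemble at each grid timestamp is the
#' median of non-outlier records across trees.
#'
#' @param bands list of [band_series()] on a common grid.
#' @return tibble `time`, `t_band`.
#' @export
ensemble_band_temp <- function(bands) {
  time <- bands[[1]]$time
  tb <- vapply(bands, function(b) {
    if (!identical(as.numeric(b$time), as.numeric(time))) {
      stop("ensemble_band_temp: bands must share one grid")
    }
    b$band_temp
  }, numeric(length(time)))
  tb <- matrix(tb, nrow = length(time))
  bin <- time_of_day_bin(time)
  for (b in unique(bin)) {
    rows <- which(bin == b)
    vals <- tb[rows, , drop = FALSE]
    v <- vals[!is.na(vals)]
    if (length(v) >= 4) {
      q <- quantile(v, c(0.25, 0.75), type = 7, names = FALSE)
      iqr <- q[2] - q[1]
      out <- !is.na(vals) & (vals < q[1] - 1.5 * iqr | vals > q[2] + 1.5 * iqr)
      vals[out] <- NA_real_
      tb[rows, ] <- vals
    }
  }
  ens <- apply(tb, 1, function(r) {
    r <- r[!is.na(r)]
    if (!length(r)) NA_real_ else median(r)
  })
  tibble::tibble(time = time, t_band = ens)
}
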