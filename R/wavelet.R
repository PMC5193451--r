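# Morlet continuous wavelet transform, cross-wavelet coherence and phase.
#
# Conventions (standard Morlet, omega0 = 6):
#   psi(eta) = pi^(-1/4) exp(i omega0 eta) exp(-eta^2 / 2)
#   W_n(s)   = sum_m x_{n+m} sqrt(dt/s) psi*(m dt / s)
#   Fourier period lambda = 4 pi s / (omega0 + sqrt(2 + omega0^2))
#   COI e-folding time sqrt(2) s.
# Phase sign: arg(W_x conj(W_y)) is positive when x leads y; a copy of x
# delayed by a quarter period yields phase +pi/2.

morlet_fourier_factor <- function(omega0) 4 * pi / (omega0 + sqrt(2 + omega0^2))

morlet_kernel <- function(dt, s, omega0, trunc_eta = 8, n_max = Inf) {
  M <- min(ceiling(trunc_eta * s / dt), n_max)
  eta <- ((-M):M) * dt / s
  list(M = M,
       k = sqrt(dt / s) * pi^(-0.25) * exp(-1i * omega0 * eta - eta^2 / 2))
}

#' Morlet continuous wavelet transform
#'
#' FFT-based correlation of the (mean-removed) series with the Morlet
#' wavelet over a dyadic set of scales, zero-padded to a power of two large
#' enough that the circular convolution equals the linear one exactly.
#'
#' @param x gap-free gridded series (gap-fill before calling).
#' @param dt sampling step in days (1/96 for the 15-minute grid).
#' @param dj scale resolution in octaves (default 1/20).
#' @param period_range Fourier-period coverage in days.
#' @param omega0 Morlet angular frequency (default 6).
#' @return object of class `wavelet_field`: complex matrix `W` (scales x
#'   time), `scales`, `periods` (days), `coi` (distance of each sample to
#'   the nearer window edge, days), plus the parameters.
#' @export
morlet_cwt <- function(x, dt = 1 / 96, dj = 1 / 20, period_range = c(0.25, 4),
                       omega0 = 6) {
  if (anyNA(x)) stop("morlet_cwt: x contains gaps; gap-fill first")
  n <- length(x)
  if (n * dt < 2) stop("morlet_cwt: series shorter than 2 days")
  x <- x - mean(x)
  ff <- morlet_fourier_factor(omega0)
  s0 <- period_range[1] / ff
  J <- ceiling(log2(period_range[2] / period_range[1]) / dj)
  scales <- s0 * 2^((0:J) * dj)
  W <- matrix(0i, nrow = J + 1, ncol = n)
  for (j in seq_along(scales)) {
    kern <- morlet_kernel(dt, scales[j], omega0, n_max = n - 1)
    M <- kern$M
    np <- 2^ceiling(log2(n + 2 * M + 1))
    xp <- complex(real = c(x, rep(0, np - n)))
    bp <- complex(length.out = np)
    # b_j = k_{-j}, laid out circularly
    bp[1] <- kern$k[M + 1]
    if (M > 0) {
      bp[1 + seq_len(M)] <- kern$k[M + 1 - seq_len(M)]
      bp[np + 1 - seq_len(M)] <- kern$k[M + 1 + seq_len(M)]
    }
    conv <- fft(fft(xp) * fft(bp), inverse = TRUE) / np
    W[j, ] <- conv[seq_len(n)]
  }
  idx <- seq_len(n)
  structure(list(W = W, scales = scales, periods = scales * ff,
                 dt = dt, dj = dj, omega0 = omega0, n = n,
                 coi = pmin(idx - 1, n - idx) * dt),
            class = "wavelet_field")
}

#' Direct time-domain Morlet CWT (reference implementation)
#'
#' Brute-force correlation used as an independent check of the FFT path;
#' O(n^2) per scale, intended for short series.
#'
#' @inheritParams morlet_cwt
#' @param s single scale (days).
#' @return complex vector along `x`.
#' @export
morlet_cwt_direct <- function(x, dt, s, omega0 = 6) {
  x <- x - mean(x)
  n <- length(x)
  kern <- morlet_kernel(dt, s, omega0, n_max = n - 1)
  M <- kern$M
  vapply(seq_len(n), function(i) {
    m <- max(1 - i, -M):min(n - i, M)
    sum(x[i + m] * kern$k[m + M + 1])
  }, complex(1))
}

# smooth a real matrix (scales x time) in time with a per-scale boxcar of
# width ~ scale/dt samples, then across scales with a boxcar spanning
# `octaves` octaves; partial windows are renormalized at the edges
smooth_field <- function(A, scales, dt, dj, octaves = 0.6) {
  for (j in seq_along(scales)) {
    w <- max(1L, round(scales[j] / dt))
    if (w %% 2L == 0L) w <- w + 1L
    A[j, ] <- boxcar_mean(A[j, ], w)
  }
  h <- max(0L, round(octaves / dj / 2))
  if (h > 0) {
    J <- nrow(A)
    cs <- apply(rbind(0, A), 2, cumsum)
    lo <- pmax(seq_len(J) - h, 1L)
    hi <- pmin(seq_len(J) + h, J)
    A <- (cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]) / (hi - lo + 1)
  }
  A
}

smooth_complex <- function(Z, scales, dt, dj, octaves = 0.6) {
  complex(real = smooth_field(Re(Z), scales, dt, dj, octaves),
          imaginary = smooth_field(Im(Z), scales, dt, dj, octaves))
}

#' Wavelet coherence and phase between two series
#'
#' Computes the Morlet cross-spectrum W_xy = W_x conj(W_y), smooths in time
#' (boxcar of width equal to the scale) and across scales (0.6-octave
#' boxcar), and returns squared coherence
#' |S(W_xy/s)|^2 / (S(|W_x|^2/s) S(|W_y|^2/s)) and phase arg S(W_xy).
#' Coherence is an R-squared analogue in \[0, 1\]; phase in (-pi, pi\] is
#' positive when `x` leads `y` (x = band temperature, y = residuals in the
#' standard use).
#'
#' @param x,y gap-free series on a common grid.
#' @param dt,dj,period_range,omega0 see [morlet_cwt()].
#' @param octaves scale-smoothing span in octaves.
#' @param xfield,yfield optionally, precomputed [morlet_cwt()] fields (e.g.
#'   reuse the ensemble-temperature field across trees).
#' @return object of class `wavelet_coherence`: matrices `coherence`,
#'   `phase` (scales x time), `scales`, `periods`, `coi`, parameters.
#' @export
wavelet_coherence_phase <- function(x = NULL, y = NULL, dt = 1 / 96, dj = 1 / 20,
                                    period_range = c(0.25, 4), omega0 = 6,
                                    octaves = 0.6,
                                    xfield = NULL, yfield = NULL) {
  if (is.null(xfield)) {
    if (is.null(x) || var(x) == 0) stop("wavelet coherence: x degenerate or missing")
    xfield <- morlet_cwt(x, dt, dj, period_range, omega0)
  }
  if (is.null(yfield)) {
    if (is.null(y) || var(y) == 0) stop("wavelet coherence: y degenerate or missing")
    yfield <- morlet_cwt(y, dt, dj, period_range, omega0)
  }
  stopifnot(identical(dim(xfield$W), dim(yfield$W)))
  scales <- xfield$scales
  inv_s <- 1 / scales
  Wxy <- xfield$W * Conj(yfield$W)
  Sxy <- smooth_complex(Wxy * inv_s, scales, xfield$dt, xfield$dj, octaves)
  Sxx <- smooth_field(Mod(xfield$W)^2 * inv_s, scales, xfield$dt, xfield$dj, octaves)
  Syy <- smooth_field(Mod(yfield$W)^2 * inv_s, scales, xfield$dt, xfield$dj, octaves)
  coh <- Mod(Sxy)^2 / (Sxx * Syy)
  coh[!is.finite(coh)] <- 0
  coh <- pmin(pmax(coh, 0), 1)
  dim(coh) <- dim(Wxy)
  phase <- Arg(smooth_complex(Wxy, scales, xfield$dt, xfield$dj, octaves))
  dim(phase) <- dim(Wxy)
  structure(list(coherence = coh, phase = phase, scales = scales,
                 periods = xfield$periods, coi = xfield$coi,
                 dt = xfield$dt, dj = xfield$dj, omega0 = omega0, n = xfield$n),
            class = "wavelet_coherence")
}

#' Gap-fill a series by linear interpolation
#'
#' Interior gaps are linearly interpolated; leading/trailing gaps take the
#' nearest observed value. Used to prepare residual series for the CWT.
#'
#' @param x series with NAs.
#' @return gap-free numeric vector (errors if everything is NA).
#' @export
gap_fill_linear <- function(x) {
  obs <- which(!is.na(x))
  if (!length(obs)) stop("gap_fill_linear: all values missing")
  if (length(obs) == length(x)) return(x)
  approx(obs, x[obs], xout = seq_along(x), method = "linear", rule = 2)$y
}
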