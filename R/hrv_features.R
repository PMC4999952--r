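# The 11 HRV parameters: time domain, frequency domain on the 7 Hz resampled
# NN tachogram, and Poincare descriptors.
#
# SD convention: population (divide by n) for sdnn and for the dispersion of
# successive differences, under which sd1 = rmssd/sqrt(2) and
# sd1^2 + sd2^2 = 2*sdnn^2 hold exactly and serve as test oracles.

TACHO_FS <- 7            # Hz, tachogram resampling rate
VLF_BAND <- c(0, 0.04)   # Hz
LF_BAND <- c(0.04, 0.15)
HF_BAND <- c(0.15, 0.40)

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Time-domain HRV parameters
#'
#' @param nn an [nn_series()] or numeric vector of NN intervals (seconds).
#' @return named list: `mean_nn`, `sdnn` (population SD), `rmssd`,
#'   `pnn50` (proportion of successive differences strictly greater than
#'   50 ms).
#' @export
time_domain <- function(nn) {
  if (inherits(nn, "nn_series")) nn <- nn$nn
  if (length(nn) < 2) stop("need at least 2 NN intervals")
  d <- diff(nn)
  list(mean_nn = mean(nn),
       sdnn = pop_sd(nn),
       rmssd = sqrt(mean(d^2)),
       pnn50 = mean(abs(d) > 0.050))
}

#' Resample an NN series to a uniform 7 Hz tachogram
#'
#' Each NN interval is attached to the time of the beat that ends it; the
#' resulting irregular series is cubic-spline interpolated and sampled at
#' exactly 7 Hz over the interior span of the beats.
#'
#' @param nn an [nn_series()] (or numeric NN vector with `beat_times`).
#' @param beat_times beat times in seconds (only when `nn` is a bare vector).
#' @return object of class `tachogram`: `values` (seconds), `fs`, `t`
#'   (sample times), `detrended` flag.
#' @export
resample_tachogram <- function(nn, beat_times = NULL) {
  if (inherits(nn, "nn_series")) {
    beat_times <- nn$beat_times
    nn <- nn$nn
  }
  if (length(nn) < 4) stop("too few beats for spline resampling")
  anchors <- beat_times[-1]
  f <- splinefun(anchors, nn, method = "natural")
  t <- seq(anchors[1], anchors[length(anchors)], by = 1 / TACHO_FS)
  structure(list(values = f(t), fs = TACHO_FS, t = t, detrended = FALSE),
            class = "tachogram")
}

#' High-pass detrending of a tachogram
#'
#' Smoothness-priors detrending: the trend is the solution of
#' `(I + lambda^2 D2' D2) z = x` (second-difference penalty) and is
#' subtracted, acting as a high-pass filter with -3 dB near `fc`.  A constant
#' maps to (numerically) zero and in-band oscillations (>= 0.15 Hz) pass with
#' gain above 0.95.
#'
#' @param tacho a `tachogram` from [resample_tachogram()].
#' @param fc target -3 dB corner frequency in Hz (default 0.035, just below
#'   the VLF/LF boundary).
#' @return the detrended `tachogram`.
#' @export
detrend_highpass <- function(tacho, fc = 0.035) {
  stopifnot(inherits(tacho, "tachogram"))
  x <- tacho$values
  n <- length(x)
  if (n < 4) stop("tachogram too short to detrend")
  # -3 dB where lambda * (2 sin(omega/2))^2 = 1
  lambda <- 1 / (2 * sin(pi * fc / tacho$fs))^2
  # A = I + lambda^2 * D2'D2 is pentadiagonal symmetric positive definite
  l2 <- lambda^2
  d0 <- 1 + l2 * c(1, 5, rep(6, n - 4), 5, 1)
  d1 <- l2 * c(-2, rep(-4, n - 3), -2)
  d2 <- l2 * rep(1, n - 2)
  trend <- .penta_solve(d0, d1, d2, x)
  tacho$values <- x - trend
  tacho$detrended <- TRUE
  tacho
}

#' Welch band powers of a tachogram
#'
#' PSD by Welch's method (512-sample periodic Hann segments, 50% overlap,
#' window-power normalization) and trapezoidal integration over the VLF
#' (0-0.04 Hz), LF (0.04-0.15 Hz) and HF (0.15-0.4 Hz) bands.
#'
#' @param tacho a detrended `tachogram`.
#' @param nperseg Welch segment length (default 512; automatically shrunk to
#'   the largest power of two below the signal length, with a warning).
#' @return named list `vlf`, `lf`, `hf` (s^2) and `lf_hf` (`NA` when
#'   `hf == 0`).
#' @export
welch_band_powers <- function(tacho, nperseg = 512) {
  stopifnot(inherits(tacho, "tachogram"))
  if (!isTRUE(tacho$detrended))
    warning("computing band powers on a non-detrended tachogram")
  p <- welch_psd(tacho$values, tacho$fs, nperseg = nperseg)
  vlf <- band_power(p$freq, p$psd, VLF_BAND[1], VLF_BAND[2])
  lf <- band_power(p$freq, p$psd, LF_BAND[1], LF_BAND[2])
  hf <- band_power(p$freq, p$psd, HF_BAND[1], HF_BAND[2])
  list(vlf = vlf, lf = lf, hf = hf,
       lf_hf = if (hf > 0) lf / hf else NA_real_)
}

#' Poincare descriptors
#'
#' `sd1` is the dispersion of successive-interval differences scaled by
#' `1/sqrt(2)` (equal to `rmssd/sqrt(2)` under the package's population
#' convention); `sd2 = sqrt(max(0, 2*sdnn^2 - sd1^2))` is the dispersion
#' along the line of identity.
#'
#' @param nn an [nn_series()] or numeric vector (>= 3 intervals).
#' @return named list `sd1`, `sd2`, `sd1_sd2` (`NA` when `sd2 == 0`).
#' @export
poincare <- function(nn) {
  if (inherits(nn, "nn_series")) nn <- nn$nn
  if (length(nn) < 3) stop("need at least 3 NN intervals")
  d <- diff(nn)
  sd1 <- sqrt(mean(d^2) / 2)
  sd2 <- sqrt(max(0, 2 * pop_sd(nn)^2 - sd1^2))
  list(sd1 = sd1, sd2 = sd2,
       sd1_sd2 = if (sd2 > 0) sd1 / sd2 else NA_real_)
}

#' All 11 HRV parameters for one window
#'
#' Composes [time_domain()], [resample_tachogram()], [detrend_highpass()],
#' [welch_band_powers()] and [poincare()]; deterministic for fixed input.
#'
#' @param nn an [nn_series()].
#' @return named list of the 11 HRV fields in [feature_names()] order.
#' @export
hrv_vector <- function(nn) {
  stopifnot(inherits(nn, "nn_series"))
  td <- time_domain(nn)
  bands <- welch_band_powers(detrend_highpass(resample_tachogram(nn)))
  pc <- poincare(nn)
  c(td, bands, pc)
}
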