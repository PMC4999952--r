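# The 3 respiratory-rate-variability parameters: mean, SD and coefficient of
# variation (x100) of breath-to-breath periods measured between positive
# peaks of the band-passed respiration trace.
#
# SD convention: sample SD (n - 1), since only on the order of a hundred
# breaths fall in a 5-minute window.

#' Band-pass filter a respiration trace
#'
#' Zero-phase 0.1-0.5 Hz band-pass (forward-backward order-4 Butterworth
#' prototype): respiration-band tones pass essentially unattenuated, DC and
#' drift as well as high-frequency noise are suppressed by more than 20 dB.
#'
#' @param resp a [waveform_record()] with channel `"RESP"` and `fs > 1` Hz.
#' @return the filtered [waveform_record()].
#' @export
bandpass_resp <- function(resp) {
  stopifnot(inherits(resp, "waveform_record"))
  if (resp$fs <= 1) stop("sampling rate too low for the 0.1-0.5 Hz passband")
  # realized as a high-pass/low-pass cascade: a direct transfer-function
  # band-pass of such narrow relative bandwidth is numerically unstable at
  # higher sampling rates
  hp <- butter_design(4, 0.1, resp$fs, "high")
  lp <- butter_design(4, 0.5, resp$fs, "low")
  resp$samples <- filtfilt(lp$b, lp$a,
                           filtfilt(hp$b, hp$a, resp$samples))
  resp
}

#' Breath-period statistics (RPdM, RPdSD, RPdV)
#'
#' Band-passes the respiration trace, detects positive peaks with the
#' delta-prominence detector (default prominence 0.2 x interquartile range,
#' recomputed per window), and summarizes the successive peak-to-peak periods.
#' Periods outside the physiologic 1-10 s range are kept but reported with a
#' warning.
#'
#' @param resp a [waveform_record()] with channel `"RESP"`.
#' @param delta peak prominence threshold in signal units; default
#'   `0.2 * IQR` of the filtered trace.
#' @return named list: `rpdm` (s), `rpdsd` (s, sample SD), `rpdv`
#'   (percent, `100 * rpdsd / rpdm`).
#' @export
rrv_vector <- function(resp, delta = NULL) {
  filtered <- bandpass_resp(resp)
  if (is.null(delta)) delta <- 0.2 * IQR(filtered$samples)
  # a near-constant trace leaves only numerical residue after filtering;
  # require the adaptive prominence to stand clear of machine noise
  floor_ <- sqrt(.Machine$double.eps) * max(abs(resp$samples), 0)
  if (!is.finite(delta) || delta <= floor_) stop("insufficient breaths")
  pk <- detect_peaks_delta(filtered, delta)
  if (length(pk$indices) < 3) stop("insufficient breaths")
  periods <- diff(pk$times)
  if (any(periods < 1 | periods > 10))
    warning("breath periods outside the plausible 1-10 s range")
  rpdm <- mean(periods)
  rpdsd <- sd(periods)
  list(rpdm = rpdm, rpdsd = rpdsd, rpdv = 100 * rpdsd / rpdm)
}
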