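# Peak detection: R-peaks in lead-II ECG and positive peaks in respiration.

#' Construct a beat series
#'
#' @param peak_times strictly increasing R-peak times in seconds.
#' @return object of class `beat_series` with elements `peak_times` and `rr`
#'   (successive differences, seconds).
#' @export
beat_series <- function(peak_times) {
  peak_times <- as.numeric(peak_times)
  if (length(peak_times) < 2) stop("insufficient beats")
  if (any(diff(peak_times) <= 0)) stop("peak times must be strictly increasing")
  structure(list(peak_times = peak_times, rr = diff(peak_times)),
            class = "beat_series")
}

#' @export
print.beat_series <- function(x, ...) {
  cat(sprintf("<beat_series> %d beats, mean RR %.3f s\n",
              length(x$peak_times), mean(x$rr)))
  invisible(x)
}

#' Detect R-peaks in a lead-II ECG
#'
#' Filter-transform-threshold chain: zero-phase band-pass (5-15 Hz),
#' differentiation, squaring, 150 ms moving-window integration, adaptive
#' signal/noise threshold with missed-beat search-back, and a 200 ms
#' refractory period.  Each fiducial is refined to the local maximum of the
#' raw signal within +/- 50 ms; peaks within 0.25 s of either window edge are
#' discarded (incomplete morphology).
#'
#' @param ecg a [waveform_record()] with channel `"ECG_II"` and duration
#'   of at least 10 s.
#' @param refractory minimum peak spacing in seconds (default 0.2).
#' @param threshold_frac fraction of the signal-noise gap used by the adaptive
#'   threshold (default 0.25).
#' @return a [beat_series()] of R-peak times (seconds from window start).
#' @export
detect_r_peaks <- function(ecg, refractory = 0.2, threshold_frac = 0.25) {
  stopifnot(inherits(ecg, "waveform_record"))
  if (ecg$channel != "ECG_II") stop("detect_r_peaks expects the ECG_II channel")
  fs <- ecg$fs
  x <- ecg$samples
  if (length(x) / fs < 10) stop("window shorter than 10 s")
  if (diff(range(x)) == 0) stop("insufficient beats")
  bp <- butter_design(3, c(5, 15), fs, "band")
  xf <- filtfilt(bp$b, bp$a, x)
  dx <- c(diff(xf), 0) * fs
  mwi <- moving_average(dx^2, max(2L, round(0.150 * fs)))

  # candidate peaks of the integrated signal, spaced >= refractory; a low
  # floor (1% of the 95th percentile) discards baseline noise wiggles early
  cand <- which(diff(sign(diff(mwi))) < 0) + 1L
  cand <- cand[mwi[cand] > 0.01 * quantile(mwi, 0.95)]
  if (length(cand) == 0) stop("insufficient beats")
  keep <- logical(length(cand))
  last <- -Inf
  ord <- seq_along(cand)
  for (i in ord) {                    # greedy in time, refractory on candidates
    if ((cand[i] - last) / fs >= refractory * 0.5) {
      keep[i] <- TRUE
      last <- cand[i]
    } else if (mwi[cand[i]] > mwi[last]) {
      keep[which(cand == last)] <- FALSE
      keep[i] <- TRUE
      last <- cand[i]
    }
  }
  cand <- cand[keep]

  # adaptive signal/noise levels (Pan-Tompkins style running estimates)
  init <- mwi[seq_len(min(length(mwi), round(2 * fs)))]
  spki <- max(init)
  npki <- mean(init) / 2
  thr <- npki + threshold_frac * (spki - npki)
  fiducial <- integer(length(cand))
  nfid <- 0L
  rr_avg <- NA_real_
  last_t <- -Inf
  for (i in seq_along(cand)) {
    p <- cand[i]
    v <- mwi[p]
    if (v > thr && (p - last_t) / fs >= refractory) {
      nfid <- nfid + 1L
      fiducial[nfid] <- p
      spki <- 0.125 * v + 0.875 * spki
      if (nfid >= 2L) {
        j <- max(1L, nfid - 8L)
        rr_avg <- (fiducial[nfid] - fiducial[j]) / ((nfid - j) * fs)
      }
      last_t <- p
    } else {
      npki <- 0.125 * v + 0.875 * npki
      # search-back: if a long gap has opened, accept the best candidate
      # above half threshold inside it
      if (!is.na(rr_avg) && (p - last_t) / fs > 1.66 * rr_avg) {
        gap <- cand[cand > last_t & cand <= p]
        gap <- gap[mwi[gap] > thr / 2 & (gap - last_t) / fs >= refractory]
        if (length(gap)) {
          b <- gap[which.max(mwi[gap])]
          nfid <- nfid + 1L
          fiducial[nfid] <- b
          spki <- 0.25 * mwi[b] + 0.75 * spki
          last_t <- b
        }
      }
    }
    thr <- npki + threshold_frac * (spki - npki)
  }
  fiducial <- fiducial[seq_len(nfid)]
  if (length(fiducial) < 2) stop("insufficient beats")

  # the integrator window is trailing, so its peak lags the QRS: first find
  # the band-passed QRS apex in the 150 ms preceding each fiducial, then
  # refine to the raw-signal local maximum within +/- 50 ms
  half <- as.integer(round(0.050 * fs))
  lag <- as.integer(round(0.150 * fs))
  n <- length(x)
  peaks <- vapply(fiducial, function(p) {
    a <- max(1L, as.integer(p) - lag)
    b <- min(n, as.integer(p))
    q <- a + which.max(xf[a:b]) - 1L
    a <- max(1L, q - half)
    b <- min(n, q + half)
    a + which.max(x[a:b]) - 1L
  }, 0L)
  peaks <- sort(unique(peaks))
  # refractory on refined peaks: keep the taller of any conflicting pair
  if (length(peaks) > 1) {
    out <- peaks[1]
    for (p in peaks[-1]) {
      if ((p - tail(out, 1)) / fs >= refractory) out <- c(out, p)
      else if (x[p] > x[tail(out, 1)]) out[length(out)] <- p
    }
    peaks <- out
  }
  edge <- 0.25 * fs
  peaks <- peaks[peaks > edge & peaks <= n - edge]
  if (length(peaks) < 2) stop("insufficient beats")
  beat_series((peaks - 1) / fs + ecg$t0)
}

#' Delta-prominence peak detection (alternating max/min search)
#'
#' Scans the signal keeping running extrema: a local maximum is reported once
#' the signal has dropped `delta` below it, after which the search alternates
#' to a minimum, and so on.  Equivalent to an exhaustive alternating-extremum
#' scan.
#'
#' @param signal a [waveform_record()] or numeric vector.
#' @param delta prominence threshold in signal units (> 0).
#' @return list with `indices` (1-based sample indices of maxima) and `times`
#'   (seconds, when a sampling rate is known).
#' @export
detect_peaks_delta <- function(signal, delta) {
  if (!is.finite(delta) || delta <= 0) stop("delta must be > 0")
  fs <- NA_real_
  t0 <- 0
  if (inherits(signal, "waveform_record")) {
    fs <- signal$fs
    t0 <- signal$t0
    signal <- signal$samples
  }
  mx <- -Inf; mn <- Inf
  mxpos <- NA_integer_; mnpos <- NA_integer_
  lookformax <- TRUE
  maxima <- integer(0)
  for (i in seq_along(signal)) {
    v <- signal[i]
    if (v > mx) { mx <- v; mxpos <- i }
    if (v < mn) { mn <- v; mnpos <- i }
    if (lookformax) {
      if (v < mx - delta) {
        maxima <- c(maxima, mxpos)
        mn <- v; mnpos <- i
        lookformax <- FALSE
      }
    } else if (v > mn + delta) {
      mx <- v; mxpos <- i
      lookformax <- TRUE
    }
  }
  list(indices = maxima,
       times = if (is.na(fs)) (maxima - 1) else (maxima - 1) / fs + t0)
}
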