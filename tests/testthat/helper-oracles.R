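# Independent oracles and small fixture builders shared across tests.

# Brute-force alternating-extremum scan (O(n^2), range max/min based) --
# structurally independent of the running-state detector it checks.
peaks_delta_oracle <- function(x, delta) {
  n <- length(x)
  peaks <- integer(0)
  t <- 1
  repeat {
    # trigger: first d with max(x[t..d]) - x[d] >= delta
    d <- NA_integer_
    for (j in t:n) {
      if (max(x[t:j]) - x[j] >= delta) { d <- j; break }
    }
    if (is.na(d)) break
    seg <- x[t:d]
    p <- t + which.max(seg) - 1L   # first occurrence of the max
    peaks <- c(peaks, p)
    # valley: first e >= d with x[e] - min(x[d..e]) >= delta
    e <- NA_integer_
    for (j in d:n) {
      if (x[j] - min(x[d:j]) >= delta) { e <- j; break }
    }
    if (is.na(e)) break
    t <- e
  }
  peaks
}

# Direct one-sided periodogram by explicit DFT sums (no FFT), with the same
# 1/(fs*N) scaling as an unwindowed, un-demeaned Welch segment.
dft_periodogram_oracle <- function(x, fs) {
  n <- length(x)
  k <- 0:(n %/% 2)
  psd <- vapply(k, function(kk) {
    w <- -2 * pi * kk * (0:(n - 1)) / n
    re <- sum(x * cos(w))
    im <- sum(x * sin(w))
    (re^2 + im^2) / (fs * n)
  }, 0)
  dbl <- rep(2, length(k))
  dbl[1] <- 1
  if (n %% 2 == 0) dbl[length(k)] <- 1
  list(freq = k * fs / n, psd = psd * dbl)
}

# Pairwise Mann-Whitney AUC by explicit double loop (independent of both
# the vectorized auc_brute and the ROC integration).
auc_pairwise_oracle <- function(scores, labels) {
  sp <- scores[labels == 1]
  sn <- scores[labels == -1]
  tot <- 0
  for (a in sp) for (b in sn)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(sp) * length(sn))
}

# A clean synthetic ECG window with known beat times.
make_ecg_fixture <- function(mean_nn = 0.8, sdnn = 0.04, duration = 60,
                             fs = 250, noise_sd = 0, seed = 1) {
  rr <- gen_rr_series(mean_nn, sdnn, duration = duration, seed = seed)
  ecg <- gen_ecg_from_rr(rr$beat_times, fs, noise_sd, seed = seed + 1,
                         duration = duration)
  list(ecg = ecg, beat_times = rr$beat_times, rr = rr$rr)
}

# Bare tachogram from a numeric vector (for filter-response tests).
make_tacho <- function(values, detrended = FALSE) {
  structure(list(values = values, fs = 7,
                 t = seq_along(values) / 7, detrended = detrended),
            class = "tachogram")
}

# Match detected peak times against ground truth within a tolerance;
# returns recall and precision.
match_peaks <- function(detected, truth, tol = 0.02) {
  if (length(truth) == 0 || length(detected) == 0)
    return(c(recall = 0, precision = 0))
  d <- abs(outer(detected, truth, "-"))
  c(recall = mean(apply(d, 2, min) <= tol),
    precision = mean(apply(d, 1, min) <= tol))
}
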