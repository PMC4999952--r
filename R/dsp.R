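# Digital signal processing primitives: Butterworth design via the bilinear
# transform, zero-phase filtering, and Welch's periodogram.  These back the
# detector band-pass (5-15 Hz), the respiration band-pass (0.1-0.5 Hz) and the
# tachogram spectral analysis; none of the mainstream DSP packages are assumed.

poly_from_roots <- function(r) {
  p <- complex(real = 1)
  for (rt in r) p <- c(p, 0i) - c(0i, p * rt)
  p
}

# Butterworth analog prototype poles (unit cutoff, Hurwitz).
butter_prototype <- function(n) {
  m <- seq(-n + 1, n - 1, by = 2)
  -exp(1i * pi * m / (2 * n))
}

#' Butterworth IIR filter design
#'
#' Designs a digital Butterworth filter by the standard analog-prototype /
#' frequency-transform / bilinear-transform route and returns transfer-function
#' coefficients.
#'
#' @param n filter order (the band-pass realization has `2n` poles).
#' @param w cutoff frequency in Hz (scalar for `"low"`/`"high"`, length-2
#'   vector for `"band"`).
#' @param fs sampling rate in Hz.
#' @param type one of `"low"`, `"high"`, `"band"`.
#' @return list with numerator `b` and denominator `a` (leading `a` term 1).
#' @export
butter_design <- function(n, w, fs, type = c("low", "high", "band")) {
  type <- match.arg(type)
  if (n < 1) stop("filter order must be >= 1")
  if (any(w <= 0) || any(w >= fs / 2))
    stop("cutoff frequencies must lie strictly inside (0, fs/2)")
  warped <- 2 * fs * tan(pi * w / fs)
  p <- butter_prototype(n)
  z <- complex(0)
  k <- 1
  if (type == "low") {
    wo <- warped[1]
    p <- p * wo
    k <- wo^n
  } else if (type == "high") {
    wo <- warped[1]
    k <- Re(prod(-p))
    p <- wo / p
    z <- rep(complex(real = 0), n)
  } else {
    if (length(w) != 2 || w[2] <= w[1])
      stop("band-pass design needs w = c(lo, hi) with lo < hi")
    bw <- warped[2] - warped[1]
    wo <- sqrt(warped[1] * warped[2])
    plp <- p * bw / 2
    disc <- sqrt(plp^2 - wo^2)
    p <- c(plp + disc, plp - disc)
    z <- rep(complex(real = 0), n)
    k <- bw^n
  }
  # bilinear transform
  fs2 <- 2 * fs
  kd <- k * Re(prod(fs2 - z) / prod(fs2 - p))
  zd <- (fs2 + z) / (fs2 - z)
  pd <- (fs2 + p) / (fs2 - p)
  zd <- c(zd, rep(complex(real = -1), length(pd) - length(zd)))
  b <- Re(poly_from_roots(zd)) * kd
  a <- Re(poly_from_roots(pd))
  list(b = b / a[1], a = a / a[1])
}

# Steady-state initial conditions for a step input of unit height
# (direct-form II transposed), so filtfilt startup transients vanish.
lfilter_zi <- function(b, a) {
  nf <- max(length(a), length(b))
  b <- c(b, rep(0, nf - length(b)))
  a <- c(a, rep(0, nf - length(a)))
  if (nf == 1) return(numeric(0))
  A <- matrix(0, nf - 1, nf - 1)
  A[1, ] <- -a[-1]
  if (nf > 2) A[cbind(2:(nf - 1), 1:(nf - 2))] <- 1
  B <- b[-1] - a[-1] * b[1]
  # the system can be extremely ill-conditioned for narrow-band filters;
  # LAPACK still returns the usable steady state, so skip the rcond guard
  solve(diag(nf - 1) - t(A), B, tol = 0)
}

apply_iir <- function(b, a, x, zi = NULL) {
  nf <- max(length(a), length(b))
  if (is.null(zi)) zi <- rep(0, nf - 1)
  .iir_filter(b, a, x, zi)
}

#' Zero-phase filtering (forward-backward)
#'
#' Applies an IIR filter forwards and backwards with odd-reflection edge
#' padding and steady-state initial conditions, giving zero phase distortion
#' and a squared magnitude response.
#'
#' @param b,a transfer-function coefficients as from [butter_design()].
#' @param x numeric signal.
#' @return filtered signal, same length as `x`.
#' @export
filtfilt <- function(b, a, x) {
  n <- length(x)
  padlen <- min(3 * (max(length(a), length(b)) - 1) * 4, n - 1)
  if (n <= padlen) stop("signal too short for the requested filter")
  ext <- c(2 * x[1] - x[(padlen + 1):2], x, 2 * x[n] - x[(n - 1):(n - padlen)])
  zi <- lfilter_zi(b, a)
  y <- apply_iir(b, a, ext, zi * ext[1])
  y <- rev(apply_iir(b, a, rev(y), zi * y[length(y)]))
  y[(padlen + 1):(padlen + n)]
}

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / n)

largest_pow2_below <- function(n) 2^floor(log2(n))

#' Welch power spectral density
#'
#' Averaged modified periodogram with window-power normalization: the integral
#' of the one-sided PSD over frequency equals the signal variance for a long
#' stationary signal.
#'
#' @param x numeric signal.
#' @param fs sampling rate in Hz.
#' @param nperseg segment length (default 512; shrunk with a warning to the
#'   largest power of two not exceeding `length(x)` when the signal is short).
#' @param window `"hann"` (periodic) or `"rect"`.
#' @param overlap fractional segment overlap in `[0, 1)` (default 0.5).
#' @param demean remove each segment's mean before windowing.
#' @return list with `freq` (Hz) and `psd` (signal units squared per Hz).
#' @export
welch_psd <- function(x, fs, nperseg = 512, window = c("hann", "rect"),
                      overlap = 0.5, demean = TRUE) {
  window <- match.arg(window)
  n <- length(x)
  if (n < 8) stop("signal too short for spectral analysis")
  if (nperseg > n) {
    nperseg <- largest_pow2_below(n)
    warning(sprintf("signal shorter than requested segment; using nperseg = %d",
                    nperseg))
  }
  w <- if (window == "hann") hann_window(nperseg) else rep(1, nperseg)
  step <- max(1, round(nperseg * (1 - overlap)))
  starts <- seq(1, n - nperseg + 1, by = step)
  nfreq <- nperseg %/% 2 + 1
  acc <- numeric(nfreq)
  scale <- 1 / (fs * sum(w^2))
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1)]
    if (demean) seg <- seg - mean(seg)
    X <- fft(w * seg)[1:nfreq]
    acc <- acc + Mod(X)^2 * scale
  }
  psd <- acc / length(starts)
  # one-sided: double everything except DC (and Nyquist when nperseg is even)
  dbl <- rep(2, nfreq)
  dbl[1] <- 1
  if (nperseg %% 2 == 0) dbl[nfreq] <- 1
  list(freq = (0:(nfreq - 1)) * fs / nperseg, psd = psd * dbl)
}

#' Trapezoidal band power
#'
#' Integrates a PSD over a frequency band by the trapezoid rule on the grid
#' points falling inside the band (edges inclusive).
#'
#' @param freq,psd PSD grid as from [welch_psd()].
#' @param lo,hi band edges in Hz.
#' @return band power (signal units squared).
#' @export
band_power <- function(freq, psd, lo, hi) {
  sel <- freq >= lo & freq <= hi
  if (sum(sel) < 2) return(0)
  trapz(freq[sel], psd[sel])
}

trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

# Trailing moving average (window shortened at the left edge).
moving_average <- function(x, width) {
  n <- length(x)
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  a <- pmax(1, i - width + 1)
  (cs[i + 1] - cs[a]) / (i - a + 1)
}
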