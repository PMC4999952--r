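# Synthetic ECG + respiration cohorts with controllable HRV/RRV statistics.
#
# The generator's stated world: published group means/SDs of the 14
# parameters for the pre-VT and control groups (the package's built-in
# group_stats()), 5-minute windows, ECG at 250 Hz and respiration at 62.5 Hz
# (typical patient-monitor rates), ectopic beats at 1/min rendered as
# premature beats with preserved compensatory pause.

#' Published group statistics for the 14 parameters
#'
#' Mean and SD of every parameter for the control and pre-VT groups, in
#' package units (seconds; band powers s^2; pnn50 as a proportion; rpdv in
#' percent).  These are the generator's calibration targets.
#'
#' @return data.frame with columns `parameter`, `control_mean`, `control_sd`,
#'   `vt_mean`, `vt_sd`.
#' @export
group_stats <- function() {
  data.frame(
    parameter = feature_names(),
    control_mean = c(0.709, 0.061, 0.068, 0.209,
                     4.10e-05, 7.61e-04, 1.53e-03, 0.498,
                     0.039, 0.081, 0.466,
                     2.73, 0.721, 28.4),
    control_sd = c(0.149, 0.042, 0.053, 0.224,
                   6.54e-05, 1.16e-03, 2.02e-03, 0.372,
                   0.029, 0.057, 0.169,
                   0.817, 0.578, 5.31),
    vt_mean = c(0.718, 0.073, 0.081, 0.239,
                6.23e-05, 1.04e-03, 1.96e-03, 0.533,
                0.047, 0.098, 0.469,
                2.95, 0.915, 25.4),
    vt_sd = c(0.158, 0.045, 0.057, 0.205,
              9.81e-05, 1.15e-03, 2.16e-03, 0.435,
              0.032, 0.060, 0.164,
              0.871, 0.868, 3.56))
}

#' Simulation configuration
#'
#' @param n_per_group windows per group (default 52, the study's cohort size).
#' @param duration_s window length in seconds (default 300; >= 60 required).
#' @param ecg_fs ECG sampling rate in Hz (default 250).
#' @param resp_fs respiration sampling rate in Hz (default 62.5).
#' @param ectopic_rate ectopic beats per minute (default 1).
#' @param ecg_noise_sd white-noise SD on the ECG in mV (default 0.02, i.e. 2%
#'   of the 1 mV R amplitude).
#' @param resp_noise_sd white-noise SD on the respiration trace (default
#'   0.02, arbitrary units on a unit-amplitude signal).
#' @param seed master RNG seed (mandatory).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_per_group = 52, duration_s = 300, ecg_fs = 250,
                       resp_fs = 62.5, ectopic_rate = 1,
                       ecg_noise_sd = 0.02, resp_noise_sd = 0.02, seed) {
  if (missing(seed)) stop("a seed is mandatory for reproducibility")
  if (duration_s < 60) stop("duration must be at least 60 s")
  structure(list(n_per_group = n_per_group, duration_s = duration_s,
                 ecg_fs = ecg_fs, resp_fs = resp_fs,
                 ectopic_rate = ectopic_rate, ecg_noise_sd = ecg_noise_sd,
                 resp_noise_sd = resp_noise_sd, seed = seed),
            class = "sim_config")
}

sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

#' Generate an RR series from the IPFM forward model
#'
#' Beats fire whenever the integral of `(1 + m(t))` crosses multiples of the
#' mean beat period.  The modulation `m(t)` is the sum of an LF tone
#' (0.095 Hz), an HF tone (0.275 Hz) and band-limited VLF drift noise, with
#' component amplitudes scaled (including a sinc correction for the
#' interval-averaging of the beat process) so the realized SDNN approximates
#' `sdnn_target` and the realized mean RR is within ~2% of `mean_nn`.
#'
#' @param mean_nn target mean beat period in seconds (0.3-2.0).
#' @param sdnn_target target SDNN in seconds (must not exceed
#'   `0.5 * mean_nn`).
#' @param lf_frac,hf_frac fractions of the modulation variance assigned to
#'   the LF and HF tones (each in `[0, 1]`, sum <= 1; the remainder is
#'   band-limited VLF drift noise, 0.004-0.030 Hz, which contributes to SDNN
#'   but stays out of the LF/HF analysis bands and is largely removed by
#'   detrending -- mirroring published cohorts where VLF+LF+HF power accounts
#'   for only part of SDNN^2).
#' @param duration window length in seconds.
#' @param seed RNG seed.
#' @param f_lf,f_hf tone frequencies in Hz (mid-band, incommensurate).
#' @return list with `beat_times` (seconds) and `rr` (successive intervals).
#' @export
gen_rr_series <- function(mean_nn, sdnn_target, lf_frac = 0.2, hf_frac = 0.4,
                          duration = 300, seed = 1,
                          f_lf = 0.095, f_hf = 0.275) {
  if (mean_nn < 0.3 || mean_nn > 2.0) stop("mean_nn must lie in [0.3, 2] s")
  if (lf_frac < 0 || hf_frac < 0 || lf_frac + hf_frac > 1)
    stop("lf_frac/hf_frac must be nonnegative with sum <= 1")
  if (sdnn_target > 0.5 * mean_nn)
    stop("infeasible target: sdnn_target > 0.5 * mean_nn")
  dt <- 0.01
  tg <- seq(0, duration + 2 * mean_nn, by = dt)
  sig_m <- sdnn_target / mean_nn
  m <- with_seed(seed, {
    ph <- runif(2, 0, 2 * pi)
    a_lf <- sig_m * sqrt(2 * lf_frac) / sinc(f_lf * mean_nn)
    a_hf <- sig_m * sqrt(2 * hf_frac) / sinc(f_hf * mean_nn)
    mm <- a_lf * cos(2 * pi * f_lf * tg + ph[1]) +
      a_hf * cos(2 * pi * f_hf * tg + ph[2])
    nf <- 1 - lf_frac - hf_frac
    if (nf > 1e-12 && sig_m > 0) {
      npad <- stats::nextn(length(tg))
      w <- rnorm(npad)
      W <- fft(w)
      fr <- (seq_len(npad) - 1) / (npad * dt)
      fr <- pmin(fr, 1 / dt - fr)
      keep <- fr >= 0.004 & fr <= 0.030
      if (!any(keep)) {
        # window too short for a full drift band: use the closest bin
        keep[fr > 0 & abs(fr - 0.017) == min(abs(fr[fr > 0] - 0.017))] <- TRUE
      }
      bl <- Re(fft(W * keep, inverse = TRUE))[seq_along(tg)] / npad
      bl <- bl / pop_sd(bl) * sig_m * sqrt(nf)
      mm <- mm + bl
    }
    mm
  })
  m <- pmin(pmax(m, -0.9), 0.7)  # keep instantaneous rate physiologic
  y <- cumsum(c(0, (1 + m[-1] + 1 + m[-length(m)]) / 2 * dt))
  nbeat <- floor(y[length(y)] / mean_nn)
  levels <- seq_len(nbeat) * mean_nn
  beat_times <- approx(y, tg, xout = levels, ties = "ordered")$y
  beat_times <- c(0, beat_times[is.finite(beat_times)])
  beat_times <- beat_times[beat_times <= duration]
  if (length(beat_times) < 2) stop("degenerate beat series")
  list(beat_times = beat_times, rr = diff(beat_times))
}

# P-QRS-T template: offsets (s), widths (s), amplitudes (mV)
ECG_TEMPLATE <- list(mu = c(-0.20, -0.030, 0, 0.030, 0.22),
                     sigma = c(0.025, 0.010, 0.012, 0.010, 0.050),
                     amp = c(0.12, -0.10, 1.00, -0.15, 0.30))

#' Render an ECG waveform from beat times
#'
#' Sum of stereotyped Gaussian P-QRS-T bumps centered on each beat time plus
#' white noise; the R apex falls within one sample of each beat time.
#'
#' @param beat_times beat times in seconds (all RR >= 0.25 s).
#' @param fs sampling rate in Hz (>= 100).
#' @param noise_sd white-noise SD in mV.
#' @param seed RNG seed for the noise.
#' @param duration window length in seconds (default: last beat + 0.5 s).
#' @return ECG [waveform_record()].
#' @export
gen_ecg_from_rr <- function(beat_times, fs = 250, noise_sd = 0, seed = 1,
                            duration = NULL) {
  if (length(beat_times) == 0) stop("empty beat list")
  if (fs < 100) stop("fs must be >= 100 Hz")
  if (any(diff(beat_times) < 0.25))
    stop("overlapping beats (RR < 0.25 s)")
  if (is.null(duration)) duration <- max(beat_times) + 0.5
  n <- round(duration * fs)
  x <- numeric(n)
  tpl <- ECG_TEMPLATE
  # one precomputed P-QRS-T template, overlap-added at each beat (centers
  # snapped to the nearest sample: apex error <= half a sample period)
  lo <- min(tpl$mu - 4 * tpl$sigma)
  hi <- max(tpl$mu + 4 * tpl$sigma)
  tt <- seq(floor(lo * fs), ceiling(hi * fs)) / fs
  shape <- rowSums(vapply(seq_along(tpl$mu), function(j)
    tpl$amp[j] * exp(-(tt - tpl$mu[j])^2 / (2 * tpl$sigma[j]^2)),
    numeric(length(tt))))
  off0 <- floor(lo * fs)
  L <- length(shape)
  for (bt in beat_times) {
    i0 <- round(bt * fs) + 1L + off0
    a <- max(1L, i0); b <- min(n, i0 + L - 1L)
    if (a > b) next
    x[a:b] <- x[a:b] + shape[(a - i0 + 1L):(b - i0 + 1L)]
  }
  if (noise_sd > 0) x <- x + with_seed(seed, rnorm(n, 0, noise_sd))
  waveform_record(x, fs, "ECG_II")
}

#' Inject premature (ectopic) beats
#'
#' A Poisson number of interior beats (rate per minute) is advanced by 40% of
#' the preceding RR interval; the following sinus beat is unchanged, so each
#' ectopic produces the classic short interval + compensatory pause pair.
#'
#' @param beat_times beat times in seconds.
#' @param rate_per_min expected ectopics per minute (>= 0).
#' @param seed RNG seed.
#' @return list with perturbed `beat_times` and `ectopic_idx` (ground-truth
#'   indices of the displaced beats).
#' @export
inject_ectopics <- function(beat_times, rate_per_min, seed = 1) {
  if (rate_per_min < 0) stop("rate must be >= 0")
  nb <- length(beat_times)
  if (rate_per_min == 0 || nb < 4)
    return(list(beat_times = beat_times, ectopic_idx = integer(0)))
  dur_min <- (max(beat_times) - min(beat_times)) / 60
  rr_prev <- c(Inf, diff(beat_times))
  idx <- with_seed(seed, {
    k <- min(rpois(1, rate_per_min * dur_min), (nb - 2) %/% 2)
    # eligible beats: the shortened interval (60% of the preceding RR) must
    # remain physiologic/renderable
    elig <- which(0.6 * rr_prev >= 0.27)
    elig <- elig[elig > 1 & elig < nb]
    if (k == 0 || length(elig) == 0) integer(0) else {
      cand <- sample(elig)
      sel <- integer(0)
      for (c0 in cand) {                 # no two ectopics on adjacent beats
        if (length(sel) == k) break
        if (all(abs(sel - c0) > 1)) sel <- c(sel, c0)
      }
      sort(sel)
    }
  })
  bt <- beat_times
  bt[idx] <- bt[idx] - 0.4 * (beat_times[idx] - beat_times[idx - 1])
  list(beat_times = bt, ectopic_idx = idx)
}

truncnorm_moments <- function(mu, sigma, lo, hi) {
  a <- (lo - mu) / sigma; b <- (hi - mu) / sigma
  Z <- pnorm(b) - pnorm(a)
  da <- dnorm_safe(a); db <- dnorm_safe(b)
  m <- mu + sigma * (da - db) / Z
  v <- sigma^2 * (1 + (a * da - b * db) / Z - ((da - db) / Z)^2)
  c(mean = m, sd = sqrt(max(v, 0)))
}

# Latent (mu, sigma) of a normal truncated to [lo, hi] whose realized mean
# and SD equal the targets; errors when the targets are infeasible on the
# truncation range.
truncnorm_match <- function(target_mean, target_sd, lo, hi) {
  obj <- function(par) {
    mo <- truncnorm_moments(par[1], exp(par[2]), lo, hi)
    (mo["mean"] - target_mean)^2 / target_sd^2 +
      (mo["sd"] - target_sd)^2 / target_sd^2
  }
  fit <- optim(c(target_mean, log(target_sd)), obj,
               control = list(reltol = 1e-14, maxit = 2000))
  if (fit$value > 1e-8)
    stop("infeasible breath-period targets for the resolvable range")
  list(mu = fit$par[1], sigma = exp(fit$par[2]))
}

# Shortest breath period the 0.1-0.5 Hz analysis band can resolve: peaks
# spaced more tightly merge after band-pass filtering.
RESP_MIN_PERIOD <- 1.6
RESP_MAX_PERIOD <- 10
# peak displacement per unit period asymmetry caused by overlapping filtered
# pulse tails (measured once from the band-pass forward model)
RESP_SHIFT_COEF <- 0.063

#' Generate a respiration waveform
#'
#' Pulse-train model of breathing: per-breath periods are drawn i.i.d. from a
#' truncated normal on the resolvable range (1.6-10 s; the mandated
#' 0.1-0.5 Hz analysis band merges peaks spaced more tightly), with latent
#' parameters moment-matched so the realized period mean and SD equal the
#' targets.  Each breath is rendered as a symmetric inspiration bump (Hann
#' pulse) centered on its breath boundary with a quiet expiratory pause in
#' between; a symmetric pulse stays symmetric through the pipeline's
#' zero-phase band-pass, so the detected positive peaks reproduce the drawn
#' peak-to-peak periods (unlike a frequency-modulated sinusoid, whose period
#' variability the narrow band-pass smooths away).
#'
#' @param rpdm_target target mean breath period in seconds (1-10).
#' @param rpdsd_target target SD of breath periods in seconds
#'   (< `rpdm_target`; must be feasible on the truncation range).
#' @param duration window length in seconds.
#' @param fs sampling rate in Hz.
#' @param seed RNG seed.
#' @param noise_sd additive white-noise SD (unit-amplitude signal).
#' @return respiration [waveform_record()].
#' @export
gen_resp <- function(rpdm_target, rpdsd_target, duration = 300, fs = 62.5,
                     seed = 1, noise_sd = 0) {
  if (rpdm_target < 1 || rpdm_target > 10)
    stop("rpdm_target must lie in [1, 10] s")
  if (rpdsd_target >= rpdm_target)
    stop("degenerate targets: rpdsd >= rpdm")
  if (rpdsd_target > 0) {
    par <- truncnorm_match(rpdm_target, rpdsd_target,
                           RESP_MIN_PERIOD, RESP_MAX_PERIOD)
  }
  periods <- with_seed(seed, {
    if (rpdsd_target == 0) {
      rep(rpdm_target, ceiling((duration + 2 * rpdm_target) / rpdm_target))
    } else {
      out <- numeric(0)
      while (sum(out) < duration + 2 * rpdm_target) {
        p <- rnorm(32, par$mu, par$sigma)
        out <- c(out, p[p >= RESP_MIN_PERIOD & p <= RESP_MAX_PERIOD])
      }
      out
    }
  })
  bounds <- cumsum(c(0, periods))
  pl <- c(periods[1], periods)
  pr <- c(periods, periods[length(periods)])
  # inspiration width ~60% of the local mean period, capped so pulses never
  # overlap
  width <- pmin(0.6 * (pl + pr) / 2, 0.92 * pmin(pl, pr))
  # overlapping filtered pulse tails drag each peak toward its wider
  # neighbor by ~RESP_SHIFT_COEF * (T_right - T_left); pre-compensate so the
  # detected peaks land on the drawn boundaries
  centers <- bounds - RESP_SHIFT_COEF * (pr - pl)
  tg <- seq(0, duration - 1 / fs, by = 1 / fs)
  x <- numeric(length(tg))
  addbump <- function(c0, w, amp) {
    a <- max(1L, as.integer(floor((c0 - w / 2) * fs)) + 1L)
    b <- min(length(tg), as.integer(ceiling((c0 + w / 2) * fs)) + 1L)
    if (a > b) return()
    tt <- tg[a:b] - c0
    x[a:b] <<- x[a:b] + amp * cos(pi * tt / w)^2 * (abs(tt) <= w / 2)
  }
  for (k in seq_along(centers)) {
    if (centers[k] > duration + width[k] / 2) break
    addbump(centers[k], width[k], 1)
  }
  # negative expiration lobe filling each inter-pulse gap, sized to cancel
  # the adjacent half-pulse areas: every breath integrates to ~zero, so the
  # 0.1 Hz high-pass edge produces no undershoot ringing
  for (k in seq_len(length(centers) - 1)) {
    g0 <- centers[k] + width[k] / 2
    g1 <- centers[k + 1] - width[k + 1] / 2
    gap <- g1 - g0
    if (gap <= 0.05 || g0 > duration) next
    addbump((g0 + g1) / 2, gap, -(width[k] + width[k + 1]) / (4 * gap))
  }
  if (noise_sd > 0) x <- x + with_seed(seed + 1, rnorm(length(x), 0, noise_sd))
  waveform_record(x, fs, "RESP")
}

# Exact truncated-normal sampling by inverse CDF (robust in the tails).
rtrunc_norm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  if (sd <= 0) return(rep(mean, n))
  pa <- pnorm((lo - mean) / sd)
  pb <- pnorm((hi - mean) / sd)
  if (pb - pa < 1e-14)
    stop("infeasible draws: no mass inside the truncation bounds")
  pmin(pmax(qnorm(runif(n, pa, pb)) * sd + mean, lo), hi)
}

# Mean-matched truncated normal: shifts the latent mean so the truncated
# distribution's expectation equals `target`.
rtrunc_norm_meanmatch <- function(n, target, sd, lo = -Inf, hi = Inf) {
  if (sd <= 0) return(rep(target, n))
  tmean <- function(mu) {
    a <- (lo - mu) / sd; b <- (hi - mu) / sd
    den <- pnorm(b) - pnorm(a)
    out <- mu + sd * (dnorm_safe(a) - dnorm_safe(b)) / den
    # far-tail underflow: the truncated mass collapses onto the near bound
    if (!is.finite(out) || den < 1e-12) out <- if (a > 0) lo else hi
    out
  }
  f <- function(mu) tmean(mu) - target
  span <- 4 * sd + 1e-9
  while (f(target - span) > 0 || f(target + span) < 0) {
    span <- 2 * span
    if (span > 1e6 * (sd + abs(target)))
      stop("mean-matched truncation: target unattainable on [lo, hi]")
  }
  mu <- uniroot(f, c(target - span, target + span), tol = 1e-12)$root
  rtrunc_norm(n, mu, sd, lo, hi)
}

dnorm_safe <- function(x) ifelse(is.finite(x), stats::dnorm(x), 0)

rpdm_rpdv_feasible <- function(rpdm, rpdv) {
  rpdm * rpdv / 100 < 0.85 * (rpdm - RESP_MIN_PERIOD)
}

# The (rpdm, rpdv) pair must satisfy the breath-period feasibility
# constraint; plain pair-rejection sampling would bias both group means, so
# the latent means are calibrated once by fixed-seed Monte Carlo such that
# the accepted draws reproduce the target means.
calibrate_rpdm_rpdv <- function(m_rpdm, s_rpdm, m_rpdv, s_rpdv) {
  lat <- c(m_rpdm, m_rpdv)
  with_seed(860301, {
    u1 <- runif(20000); u2 <- runif(20000)
    for (it in 1:12) {
      rpdm <- qnorm(u1 * (pnorm((8 - lat[1]) / s_rpdm) -
                            pnorm((2 - lat[1]) / s_rpdm)) +
                      pnorm((2 - lat[1]) / s_rpdm)) * s_rpdm + lat[1]
      rpdv <- qnorm(u2 * (pnorm((60 - lat[2]) / s_rpdv) -
                            pnorm((2 - lat[2]) / s_rpdv)) +
                      pnorm((2 - lat[2]) / s_rpdv)) * s_rpdv + lat[2]
      ok <- rpdm_rpdv_feasible(rpdm, rpdv)
      if (mean(ok) < 0.01) stop("infeasible rpdm/rpdv group statistics")
      lat <- lat + 0.9 * c(m_rpdm - mean(rpdm[ok]), m_rpdv - mean(rpdv[ok]))
    }
    lat
  })
}

# One feasible (rpdm, rpdv) pair from calibrated latent means.
draw_rpdm_rpdv <- function(lat, s_rpdm, s_rpdv) {
  for (try in 1:100) {
    rpdm <- rtrunc_norm(1, lat[1], s_rpdm, 2, 8)
    rpdv <- rtrunc_norm(1, lat[2], s_rpdv, 2, 60)
    if (rpdm_rpdv_feasible(rpdm, rpdv)) return(c(rpdm, rpdv))
  }
  stop("infeasible rpdm/rpdv draws (100 rejections)")
}

#' Generate a waveform-level cohort
#'
#' For each record, group-level parameters are drawn from the [group_stats()]
#' distributions (truncated to physical ranges) and the waveforms are
#' synthesized: IPFM RR series with LF/HF modulation, injected ectopics,
#' template ECG rendering, and variable-period respiration.  Respiration is
#' parameterized by drawn `(rpdm, rpdv)` with `rpdsd = rpdm * rpdv / 100`, so
#' the published per-record rpdv distribution (including its group direction)
#' is honored.
#'
#' @param stats a [group_stats()]-shaped data.frame.
#' @param cfg a [sim_config()].
#' @return list of [labeled_window()] objects (VT windows first).
#' @export
gen_cohort <- function(stats = group_stats(), cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  seeds <- derive_seeds(cfg$seed, 2 * cfg$n_per_group * 8)
  sidx <- 0
  nextseed <- function() {
    sidx <<- sidx + 1
    seeds[sidx]
  }
  st <- function(param, group, col) {
    stats[stats$parameter == param,
          paste0(if (group > 0) "vt" else "control", "_", col)]
  }
  windows <- list()
  for (group in c(1, -1)) {
    gname <- if (group > 0) "vt" else "control"
    resp_cal <- calibrate_rpdm_rpdv(st("rpdm", group, "mean"),
                                    st("rpdm", group, "sd"),
                                    st("rpdv", group, "mean"),
                                    st("rpdv", group, "sd"))
    for (i in seq_len(cfg$n_per_group)) {
      draws <- with_seed(nextseed(), {
        # mean-matched truncation keeps the cohort means at the published
        # group means despite the physical-range bounds
        mean_nn <- rtrunc_norm_meanmatch(1, st("mean_nn", group, "mean"),
                                         st("mean_nn", group, "sd"), 0.45, 1.9)
        # cap modulation depth so the shortest modulated RR stays renderable
        sdnn <- rtrunc_norm_meanmatch(1, st("sdnn", group, "mean"),
                                      st("sdnn", group, "sd"),
                                      0.005, 0.22 * mean_nn)
        lf <- rtrunc_norm(1, st("lf", group, "mean"),
                          st("lf", group, "sd"), 1e-6, Inf)
        hf <- rtrunc_norm(1, st("hf", group, "mean"),
                          st("hf", group, "sd"), 1e-6, Inf)
        pair <- draw_rpdm_rpdv(resp_cal, st("rpdm", group, "sd"),
                               st("rpdv", group, "sd"))
        rpdm <- pair[1]
        rpdv <- pair[2]
        list(mean_nn = mean_nn, sdnn = sdnn, lf = lf, hf = hf,
             rpdm = rpdm, rpdv = rpdv)
      })
      fr <- c(draws$lf, draws$hf) / draws$sdnn^2
      if (sum(fr) > 0.85) fr <- fr * 0.85 / sum(fr)
      rr <- gen_rr_series(draws$mean_nn, draws$sdnn, fr[1], fr[2],
                          cfg$duration_s, seed = nextseed())
      ect <- inject_ectopics(rr$beat_times, cfg$ectopic_rate,
                             seed = nextseed())
      ecg <- gen_ecg_from_rr(ect$beat_times, cfg$ecg_fs, cfg$ecg_noise_sd,
                             seed = nextseed(), duration = cfg$duration_s)
      resp <- gen_resp(draws$rpdm, draws$rpdm * draws$rpdv / 100,
                       cfg$duration_s, cfg$resp_fs, seed = nextseed(),
                       noise_sd = cfg$resp_noise_sd)
      win <- labeled_window(ecg, resp, group,
                            sprintf("%s_%03d", gname, i))
      win$truth <- c(draws, list(ectopic_idx = ect$ectopic_idx,
                                 beat_times = ect$beat_times))
      windows[[length(windows) + 1]] <- win
    }
  }
  windows
}

#' Generate a feature-level cohort
#'
#' Fast, distribution-exact fixture for the classifier: the 11 non-ratio
#' parameters are drawn independently per group from mean-matched truncated
#' normals at the [group_stats()] marginals, and the three ratio parameters
#' (`lf_hf`, `sd1_sd2`, `rpdv`) are recomputed from their components for
#' internal consistency.
#'
#' @param stats a [group_stats()]-shaped data.frame.
#' @param n_per_group records per group.
#' @param seed RNG seed.
#' @return data.frame with `source_id`, the 14 feature columns, `label`.
#' @export
gen_feature_cohort <- function(stats = group_stats(), n_per_group = 52,
                               seed = 1) {
  drawn <- setdiff(feature_names(), c("lf_hf", "sd1_sd2", "rpdv"))
  lower <- c(mean_nn = 0.3, sdnn = 0, rmssd = 0, pnn50 = 0, vlf = 0,
             lf = 0, hf = 0, sd1 = 0, sd2 = 0, rpdm = 1, rpdsd = 0)
  upper <- c(mean_nn = 2, sdnn = Inf, rmssd = Inf, pnn50 = 1, vlf = Inf,
             lf = Inf, hf = Inf, sd1 = Inf, sd2 = Inf, rpdm = 10, rpdsd = Inf)
  with_seed(seed, {
    one_group <- function(group, gname) {
      cols <- lapply(drawn, function(p) {
        rtrunc_norm_meanmatch(
          n_per_group,
          stats[stats$parameter == p,
                paste0(if (group > 0) "vt" else "control", "_mean")],
          stats[stats$parameter == p,
                paste0(if (group > 0) "vt" else "control", "_sd")],
          lower[[p]], upper[[p]])
      })
      names(cols) <- drawn
      df <- as.data.frame(cols)
      df$lf_hf <- df$lf / df$hf
      df$sd1_sd2 <- df$sd1 / df$sd2
      df$rpdv <- 100 * df$rpdsd / df$rpdm
      df$source_id <- sprintf("%s_%03d", gname, seq_len(n_per_group))
      df$label <- group
      df[, c("source_id", feature_names(), "label")]
    }
    rbind(one_group(1, "vt"), one_group(-1, "control"))
  })
}
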