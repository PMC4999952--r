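# Ectopic-beat handling on RR interval series.
#
# Flagging uses a running-median rule (the deviation criterion is this
# package's choice; the upstream reference only names the IPFM model).
# Correction re-estimates flagged beat times from the integrated pulse
# frequency modulation (IPFM) model: under IPFM the k-th beat satisfies
# integral_0^{t_k} (1 + m(t)) dt = k * Tbar, so the cumulative beat index is a
# smooth, monotone function of time; flagged beats are re-placed by monotone
# cubic interpolation of beat time against beat index through the clean beats.

#' Construct an NN (normal-to-normal) series
#'
#' @param nn corrected NN intervals in seconds (all > 0).
#' @param beat_times beat times in seconds, `length(nn) + 1` of them.
#' @param ectopic_mask logical flags on the original beats (optional).
#' @param n_corrected number of re-estimated or dropped beats.
#' @return object of class `nn_series`.
#' @export
nn_series <- function(nn, beat_times, ectopic_mask = NULL, n_corrected = 0L) {
  nn <- as.numeric(nn)
  if (length(nn) < 2) stop("need at least 2 NN intervals")
  if (any(nn <= 0)) stop("NN intervals must be positive")
  if (length(beat_times) != length(nn) + 1)
    stop("beat_times must have length(nn) + 1 elements")
  structure(list(nn = nn, beat_times = as.numeric(beat_times),
                 ectopic_mask = ectopic_mask,
                 n_corrected = as.integer(n_corrected)),
            class = "nn_series")
}

#' @export
print.nn_series <- function(x, ...) {
  cat(sprintf("<nn_series> %d intervals, mean NN %.3f s, %d beat(s) corrected\n",
              length(x$nn), mean(x$nn), x$n_corrected))
  invisible(x)
}

#' Flag ectopic beats by running-median deviation
#'
#' An interval is anomalous when it deviates from the median of the (up to) 5
#' nearest not-yet-anomalous intervals by more than `tol` (relative);
#' intervals are examined in a single deterministic left-to-right pass.  A
#' beat is flagged when it bounds an anomalous interval.
#'
#' @param beats a [beat_series()] with at least 5 intervals.
#' @param tol relative deviation threshold (default 0.2).
#' @return logical vector over beats, `TRUE` = flagged ectopic.
#' @export
flag_ectopic <- function(beats, tol = 0.2) {
  stopifnot(inherits(beats, "beat_series"))
  rr <- beats$rr
  n <- length(rr)
  if (n < 5) stop("too few intervals (need >= 5)")
  # vectorized screen: deviation against the naive (exclusion-free) local
  # median, with a conservative margin; the exact left-to-right pass with
  # flagged-interval exclusion then runs only near screened candidates
  med5 <- function(v) {
    s <- sort.int(v, method = "quick")
    k <- length(s)
    if (k %% 2 == 1) s[(k + 1) %/% 2] else (s[k %/% 2] + s[k %/% 2 + 1]) / 2
  }
  naive_med <- stats::runmed(rr, min(7L, n - 1L + n %% 2L))
  suspect <- which(abs(rr - naive_med) > 0.5 * tol * naive_med)
  bad <- logical(n)
  if (length(suspect)) {
    check <- sort(unique(pmin(pmax(
      rep(suspect, each = 21) + rep(-10:10, length(suspect)), 1), n)))
    for (i in check) {
      # collect the 5 nearest unflagged intervals by expanding outward
      nb <- integer(5)
      cnt <- 0L
      for (d in 1:(n - 1)) {
        l <- i - d
        if (l >= 1 && !bad[l]) { cnt <- cnt + 1L; nb[cnt] <- l }
        if (cnt == 5L) break
        r <- i + d
        if (r <= n && !bad[r]) { cnt <- cnt + 1L; nb[cnt] <- r }
        if (cnt == 5L) break
      }
      if (cnt == 0L) next
      med <- med5(rr[nb[seq_len(cnt)]])
      if (abs(rr[i] - med) > tol * med) bad[i] <- TRUE
    }
  }
  mask <- logical(n + 1)
  mask[which(bad)] <- TRUE       # beat starting the interval
  mask[which(bad) + 1L] <- TRUE  # beat ending the interval
  mask
}

#' Correct flagged beats with the IPFM heart-timing model
#'
#' Clean beats keep their observed times; each flagged interior beat's time is
#' re-estimated by evaluating a monotone cubic interpolant of beat time versus
#' cumulative beat index fitted through the clean beats.  Flagged beats at the
#' series edges have no two-sided support and are dropped.  With an all-false
#' mask the output intervals equal the input exactly.
#'
#' @param beats a [beat_series()].
#' @param ectopic_mask logical vector over beats, as from [flag_ectopic()].
#' @return an [nn_series()].
#' @export
correct_ectopic_ipfm <- function(beats, ectopic_mask) {
  stopifnot(inherits(beats, "beat_series"))
  t <- beats$peak_times
  nb <- length(t)
  if (length(ectopic_mask) != nb)
    stop("mask length must equal the number of beats")
  clean <- which(!ectopic_mask)
  if (length(clean) < 4) stop("fewer than 4 clean beats")
  flagged <- which(ectopic_mask)
  interior <- flagged[flagged > min(clean) & flagged < max(clean)]
  dropped <- setdiff(flagged, interior)
  est <- t
  if (length(interior)) {
    f <- splinefun(clean, t[clean], method = "hyman")
    est[interior] <- f(interior)
  }
  keep <- sort(c(clean, interior))
  tt <- est[keep]
  nn_series(diff(tt), tt,
            ectopic_mask = ectopic_mask,
            n_corrected = length(interior) + length(dropped))
}

#' Flag and correct in one step
#'
#' @inheritParams flag_ectopic
#' @return an [nn_series()].
#' @export
preprocess_rr <- function(beats, tol = 0.2) {
  correct_ectopic_ipfm(beats, flag_ectopic(beats, tol))
}
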