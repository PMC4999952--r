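test_that("time-domain parameters match hand computations", {
  td <- time_domain(c(0.8, 0.8, 0.8))
  expect_equal(unlist(td), c(mean_nn = 0.8, sdnn = 0, rmssd = 0, pnn50 = 0))
  td <- time_domain(c(0.7, 0.8))
  expect_equal(td$mean_nn, 0.75)
  expect_equal(td$rmssd, 0.1)
  expect_equal(td$pnn50, 1)
  expect_error(time_domain(0.8), "at least 2")
})

test_that("pnn50 uses strict > 50 ms and is monotone under additions", {
  expect_equal(time_domain(c(0.80, 0.85))$pnn50, 0)   # exactly 50 ms
  base <- c(0.8, 0.82, 0.8, 0.84)
  expect_gte(time_domain(c(base, 0.84 + 0.06))$pnn50,
             time_domain(base)$pnn50)
})

test_that("tachogram resampling reproduces polynomials and tones", {
  t <- cumsum(rep(0.8, 39))
  nn <- nn_series(rep(0.8, 39), c(0, t))
  ta <- resample_tachogram(nn)
  expect_equal(ta$fs, 7)
  expect_true(all(abs(ta$values - 0.8) < 1e-12))

  lin <- seq(0.7, 0.9, length.out = 39)
  bt <- cumsum(c(0, lin))
  ta <- resample_tachogram(nn_series(lin, bt))
  ref <- approx(bt[-1], lin, xout = ta$t)$y
  expect_lt(max(abs(ta$values - ref)), 1e-4)

  # 0.1 Hz modulated series shows its spectral peak at 0.1 Hz (+- one bin)
  rr <- gen_rr_series(0.8, 0.04, lf_frac = 1, hf_frac = 0, duration = 300,
                      seed = 3, f_lf = 0.1)
  ta <- detrend_highpass(resample_tachogram(nn_series(rr$rr, rr$beat_times)))
  p <- welch_psd(ta$values, 7)
  expect_lt(abs(p$freq[which.max(p$psd)] - 0.1), 7 / 512 + 1e-9)
})

test_that("detrending removes trends and passes in-band oscillations", {
  n <- 2101
  const <- make_tacho(rep(0.8, n))
  expect_lt(max(abs(detrend_highpass(const)$values)), 1e-8 * 0.8)
  t <- (seq_len(n) - 1) / 7
  s <- make_tacho(sin(2 * pi * 0.3 * t))
  out <- detrend_highpass(s)
  expect_equal(sqrt(mean(out$values^2)), sqrt(mean(s$values^2)),
               tolerance = 0.05)
  ramp <- make_tacho(seq(0, 1, length.out = n))
  expect_lt(sqrt(mean(detrend_highpass(ramp)$values^2)),
            0.05 * sqrt(mean(ramp$values^2)))
})

test_that("pure tones place their power in the correct bands", {
  t <- (0:2099) / 7
  for (case in list(list(f = 0.10, band = "lf"), list(f = 0.25, band = "hf"))) {
    a <- 0.04
    ta <- make_tacho(a * sin(2 * pi * case$f * t), detrended = TRUE)
    bp <- welch_band_powers(ta)
    tot <- bp$vlf + bp$lf + bp$hf
    expect_gte(bp[[case$band]] / tot, 0.95)
    expect_equal(tot, a^2 / 2, tolerance = 0.05)
  }
})

test_that("lf_hf is missing when HF power is zero", {
  ta <- make_tacho(rep(0, 600), detrended = TRUE)
  expect_true(is.na(welch_band_powers(ta)$lf_hf))
})

test_that("Poincare identities hold exactly (population convention)", {
  withr::with_seed(17, {
    for (i in 1:1000) {
      # sized like real 5-minute windows (the sd2 formula clamps at zero
      # for degenerate tiny series, where the identity cannot hold)
      nn <- runif(sample(100:400, 1), 0.4, 1.2)
      td <- time_domain(nn)
      pc <- poincare(nn)
      expect_equal(pc$sd1, td$rmssd / sqrt(2), tolerance = 1e-12)
      expect_equal(pc$sd1^2 + pc$sd2^2, 2 * td$sdnn^2, tolerance = 1e-12)
    }
  })
  pc <- poincare(rep(0.8, 10))
  expect_equal(pc$sd1, 0)
  expect_equal(pc$sd2, 0)
  expect_true(is.na(pc$sd1_sd2))
})

test_that("alternating series gives the textbook SD1", {
  nn <- rep(c(0.7, 0.9), 10)
  expect_equal(poincare(nn)$sd1, 0.2 / sqrt(2), tolerance = 1e-3)
})

test_that("hrv_vector is deterministic and offset invariant", {
  rr <- gen_rr_series(0.8, 0.05, duration = 300, seed = 9)
  nn <- nn_series(rr$rr, rr$beat_times)
  v1 <- hrv_vector(nn)
  v2 <- hrv_vector(nn)
  expect_identical(v1, v2)
  nn_off <- nn_series(rr$rr, rr$beat_times + 1000)
  expect_equal(hrv_vector(nn_off), v1, tolerance = 1e-9)
})

test_that("HF-only modulation yields HF-dominated spectrum", {
  rr <- gen_rr_series(0.8, 0.05, lf_frac = 0, hf_frac = 1, duration = 300,
                      seed = 13)
  v <- hrv_vector(nn_series(rr$rr, rr$beat_times))
  expect_gt(v$hf, 10 * v$lf)
})

test_that("constant series yields zero variability everywhere", {
  bt <- seq(0, 300, by = 0.8)
  v <- hrv_vector(nn_series(diff(bt), bt))
  expect_equal(v$mean_nn, 0.8)
  expect_equal(v$sdnn, 0)
  expect_equal(v$rmssd, 0)
  expect_lt(v$lf + v$hf + v$vlf, 1e-12)
})
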