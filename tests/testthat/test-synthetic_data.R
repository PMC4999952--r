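test_that("IPFM generator hits its rate and variability targets", {
  rr <- gen_rr_series(0.8, 0, duration = 120, seed = 1)
  expect_true(all(abs(rr$rr - 0.8) < 1e-6))

  rr <- gen_rr_series(0.709, 0.061, lf_frac = 0.2, hf_frac = 0.4,
                      duration = 300, seed = 42)
  expect_equal(mean(rr$rr), 0.709, tolerance = 0.02)
  expect_equal(vtpredict:::pop_sd(rr$rr), 0.061, tolerance = 0.15)

  expect_error(gen_rr_series(0.1, 0.01), "mean_nn")
  expect_error(gen_rr_series(0.8, 0.5), "infeasible")
  expect_error(gen_rr_series(0.8, 0.05, lf_frac = 0.8, hf_frac = 0.5),
               "sum <= 1")
})

test_that("generators are deterministic under a fixed seed", {
  a <- gen_rr_series(0.8, 0.05, duration = 60, seed = 7)
  b <- gen_rr_series(0.8, 0.05, duration = 60, seed = 7)
  expect_identical(a, b)
  expect_false(identical(
    a$rr, gen_rr_series(0.8, 0.05, duration = 60, seed = 8)$rr))
  r1 <- gen_resp(3, 0.5, duration = 60, seed = 7)
  expect_identical(r1, gen_resp(3, 0.5, duration = 60, seed = 7))
  e1 <- gen_ecg_from_rr(a$beat_times, noise_sd = 0.05, seed = 3)
  expect_identical(e1, gen_ecg_from_rr(a$beat_times, noise_sd = 0.05,
                                       seed = 3))
})

test_that("ECG rendering places R apexes on beat times", {
  rr <- gen_rr_series(0.8, 0.04, duration = 60, seed = 2)
  ecg <- gen_ecg_from_rr(rr$beat_times, 250, noise_sd = 0, seed = 1,
                         duration = 60)
  beats <- detect_r_peaks(ecg)
  truth <- rr$beat_times[rr$beat_times > 0.25 & rr$beat_times < 60 - 0.25]
  m <- match_peaks(beats$peak_times, truth, tol = 1 / 250 + 1e-9)
  expect_equal(unname(m["recall"]), 1)
  expect_error(gen_ecg_from_rr(numeric(0)), "empty")
  expect_error(gen_ecg_from_rr(c(0, 0.1)), "overlapping")
})

test_that("ectopic injection creates short-long pairs flagged upstream", {
  bt <- seq(0, 300, by = 0.8)
  expect_identical(inject_ectopics(bt, 0, seed = 1)$beat_times, bt)

  ect <- inject_ectopics(bt, 2, seed = 5)
  k <- length(ect$ectopic_idx)
  expect_gt(k, 2)          # ~10 expected at 2/min over 5 min
  expect_lt(k, 25)
  # each perturbed beat produces one short and one long interval
  rr2 <- diff(ect$beat_times)
  expect_equal(sum(rr2 < 0.7), k)
  expect_equal(sum(rr2 > 0.9), k)

  # flagging recovers >= 90% of injected ectopics at default tolerance
  hits <- vapply(1:10, function(s) {
    rr <- gen_rr_series(0.8, 0.04, duration = 300, seed = s)
    e <- inject_ectopics(rr$beat_times, 2, seed = s + 100)
    if (length(e$ectopic_idx) == 0) return(NA_real_)
    mask <- flag_ectopic(beat_series(e$beat_times))
    mean(mask[e$ectopic_idx])
  }, 0)
  expect_gte(mean(hits, na.rm = TRUE), 0.9)
})

test_that("respiration generator respects targets and scale property", {
  v0 <- rrv_vector(gen_resp(3, 1e-12, duration = 120, seed = 3))
  expect_lt(v0$rpdv, 1)

  v <- rrv_vector(gen_resp(2.95, 0.915, duration = 300, seed = 1))
  expect_equal(v$rpdm, 2.95, tolerance = 0.05)
  expect_equal(v$rpdsd, 0.915, tolerance = 0.20)

  vd <- rrv_vector(gen_resp(2 * 2.95, 2 * 0.915, duration = 600, seed = 1))
  expect_equal(vd$rpdm, 2 * 2.95, tolerance = 0.07 * 2 * 2.95)
  expect_equal(vd$rpdsd / vd$rpdm, v$rpdsd / v$rpdm, tolerance = 0.25)

  expect_error(gen_resp(0.5, 0.1), "rpdm_target")
  expect_error(gen_resp(3, 3), "degenerate")
})

test_that("waveform cohorts have the right size, labels and determinism", {
  cfg <- sim_config(n_per_group = 3, duration_s = 60, seed = 2)
  w <- gen_cohort(cfg = cfg)
  expect_length(w, 6)
  labs <- vapply(w, function(x) x$label, 0)
  expect_equal(sum(labs == 1), 3)
  expect_equal(sum(labs == -1), 3)
  expect_true(all(vapply(w, function(x)
    record_duration(x$ecg) == 60 && x$ecg$channel == "ECG_II" &&
      x$resp$channel == "RESP", NA)))
  w2 <- gen_cohort(cfg = cfg)
  expect_identical(w[[1]]$ecg$samples, w2[[1]]$ecg$samples)
  expect_identical(w[[4]]$resp$samples, w2[[4]]$resp$samples)
})

test_that("sim_config enforces its invariants", {
  expect_error(sim_config(n_per_group = 5), "seed")
  expect_error(sim_config(duration_s = 30, seed = 1), "60")
})

test_that("feature cohorts match the group statistics (law of large numbers)", {
  # n larger than the 1e4 of the stated check: the mean estimate for the
  # high-CV spectral powers needs ~5e4 draws to resolve 2% reliably
  f <- gen_feature_cohort(n_per_group = 50000, seed = 42)
  gs <- group_stats()
  drawn <- setdiff(feature_names(), c("lf_hf", "sd1_sd2", "rpdv"))
  for (p in drawn) {
    expect_equal(mean(f[[p]][f$label == 1]),
                 gs[gs$parameter == p, "vt_mean"],
                 tolerance = 0.02, info = p)
    expect_equal(mean(f[[p]][f$label == -1]),
                 gs[gs$parameter == p, "control_mean"],
                 tolerance = 0.02, info = p)
  }
  # ratio fields are internally consistent by construction
  expect_equal(f$lf_hf, f$lf / f$hf, tolerance = 1e-12)
  expect_equal(f$rpdv, 100 * f$rpdsd / f$rpdm, tolerance = 1e-12)
  # physical bounds respected
  expect_true(all(f$pnn50 >= 0 & f$pnn50 <= 1))
  expect_true(all(f[drawn] >= 0))
})

test_that("zero-SD feature cohorts are separable point clouds", {
  gs <- group_stats()
  gs[, c("control_sd", "vt_sd")] <- 0
  f <- gen_feature_cohort(gs, n_per_group = 20, seed = 1)
  m <- train_mlp(f[, feature_names()], f$label, 3,
                 mlp_config(lr = 0.1, max_epochs = 2000, seed = 1))
  expect_equal(mean(classify(predict(m, f[, feature_names()])) == f$label), 1)
})

test_that("feature cohorts are reproducible", {
  expect_identical(gen_feature_cohort(n_per_group = 30, seed = 5),
                   gen_feature_cohort(n_per_group = 30, seed = 5))
})
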