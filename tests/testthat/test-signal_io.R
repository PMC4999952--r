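test_that("waveform records validate their invariants", {
  expect_error(waveform_record(numeric(0), 250), "empty")
  expect_error(waveform_record(1:10, -1), "positive")
  rec <- waveform_record(rnorm(75000), 250, "ECG_II")
  expect_equal(record_duration(rec), 300)
})

test_that("CSV round-trip is bit exact and carries metadata", {
  withr::with_seed(7, {
    ecg <- waveform_record(rnorm(1000), 250, "ECG_II", t0 = 12.5)
    resp <- waveform_record(rnorm(1000), 250, "RESP", t0 = 12.5)
  })
  path <- withr::local_tempfile(fileext = ".csv")
  write_record(list(ecg, resp), path)
  back <- read_record(path, "csv")
  expect_named(back, c("ECG_II", "RESP"))
  expect_identical(back$ECG_II$samples, ecg$samples)
  expect_identical(back$RESP$samples, resp$samples)
  expect_identical(back$ECG_II$fs, 250)
  expect_identical(back$ECG_II$t0, 12.5)
  expect_identical(back$RESP$channel, "RESP")
})

test_that("CSV reader rejects degenerate or metadata-free files", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("fs=250,t0=0", "ECG_II"), path)       # zero rows
  expect_error(read_record(path, "csv"), "empty signal")
  writeLines(c("hz=250", "ECG_II", "0.5"), path)     # no fs
  expect_error(read_record(path, "csv"), "sampling rate")
  expect_error(read_record(file.path(tempdir(), "nope.csv"), "csv"),
               "not found")
})

test_that("EDF round-trip recovers signals to quantization accuracy", {
  withr::with_seed(3, {
    ecg <- waveform_record(rnorm(500), 100, "ECG_II")
    resp <- waveform_record(rnorm(250, sd = 10), 50, "RESP")
  })
  path <- withr::local_tempfile(fileext = ".edf")
  vtpredict:::write_record_edf(list(ecg, resp), path)
  back <- read_record(path, "edf")
  expect_length(back, 2)
  expect_equal(back[[1]]$fs, 100)
  expect_equal(back[[2]]$fs, 50)
  expect_equal(back[[2]]$channel, "RESP")
  # 16-bit quantization over the signal range
  qstep <- diff(range(ecg$samples)) / 65535
  expect_lt(max(abs(back[[1]]$samples[1:500] - ecg$samples)), qstep)
})

test_that("WFDB-style round-trip recovers gain-scaled samples", {
  withr::with_seed(4, x <- round(rnorm(400), 3))
  rec <- waveform_record(x, 360, "ECG_II")
  path <- withr::local_tempfile(fileext = ".hea")
  vtpredict:::write_record_wfdb(rec, path, gain = 1000)
  back <- read_record(path, "wfdb")
  expect_equal(back[[1]]$samples, x, tolerance = 1e-12)
  expect_equal(back[[1]]$fs, 360)
})

test_that("feature tables have the canonical layout and exact round-trip", {
  one <- as.data.frame(as.list(setNames(rep(0, 14), feature_names())))
  one$mean_nn <- 0.8
  one$source_id <- "w1"
  one$label <- 1
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(one, path)
  expect_identical(strsplit(readLines(path, n = 1), ",")[[1]],
                   c("source_id", feature_names(), "label"))
  expect_length(strsplit(readLines(path, n = 1), ",")[[1]], 16)

  withr::with_seed(11, {
    many <- do.call(rbind, lapply(1:104, function(i) {
      row <- as.data.frame(as.list(setNames(rexp(14), feature_names())))
      row$source_id <- sprintf("w%03d", i)
      row$label <- if (i <= 52) 1 else -1
      row
    }))
  })
  write_feature_table(many, path)
  expect_length(readLines(path), 105)  # header + 104 rows
  back <- read_feature_table(path)
  for (p in feature_names()) expect_identical(back[[p]], many[[p]])
  expect_identical(back$label, many$label)
  expect_error(write_feature_table(many[0, ], path), "empty")
})
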