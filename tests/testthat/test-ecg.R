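test_that("noise-free regular rhythm is periodic on the sample grid", {
  spec <- rhythm_spec(rr_mean = 1.0, rr_sd = 0, p_ectopic = 0, noise_sd = 0,
                      seed = 1)
  ecg <- generate_ecg(spec, 10, fs = 400)
  s <- ecg$samples
  lag <- 400  # rr_mean * fs
  interior <- (lag + 1):(length(s) - lag)
  expect_lt(max(abs(s[interior] - s[interior + lag])), 1e-10)

  # autocorrelation attains its off-zero maximum exactly at rr_mean * fs
  ac <- stats::acf(s, lag.max = 600, plot = FALSE)$acf[-1]
  expect_equal(which.max(ac[100:600]) + 99, lag)
})

test_that("generation is a pure function of (spec, duration, fs)", {
  spec <- rhythm_spec(rr_mean = 0.9, rr_sd = 0.05, p_ectopic = 0.1, seed = 42)
  a <- generate_ecg(spec, 20, fs = 400)
  b <- generate_ecg(spec, 20, fs = 400)
  expect_identical(a$samples, b$samples)
  expect_identical(a$beats, b$beats)
})

test_that("detected RR intervals recover the specified mean", {
  spec <- rhythm_spec(rr_mean = 1.0, rr_sd = 0.05, seed = 3)
  ecg <- generate_ecg(spec, 300, fs = 400)
  s <- ecg$samples
  # R peaks: local maxima above half the R amplitude
  pk <- which(s > 0.5 & s > c(-Inf, head(s, -1)) & s >= c(tail(s, -1), -Inf))
  rr <- diff(pk) / ecg$fs
  rr <- rr[rr > 0.5]  # guard against double-detected samples
  se <- sd(rr) / sqrt(length(rr))
  expect_lt(abs(mean(rr) - 1.0), 3 * se + 1e-3)
})

test_that("ectopy makes the RR histogram bimodal with a compensatory pause", {
  spec <- rhythm_spec(rr_mean = 1.0, rr_sd = 0.02, p_ectopic = 0.25, seed = 11)
  ecg <- generate_ecg(spec, 240, fs = 400)
  rr <- diff(ecg$beats$time)
  short <- rr[rr < 0.8]
  long <- rr[rr >= 0.8]
  expect_gt(length(short), 10)
  expect_gt(mean(long) - mean(short), 1.0 * (1 - 0.6) / 2)
  # premature + compensatory spans sum to 2 * rr_mean
  ect <- which(ecg$beats$class == "ectopic")
  ect <- ect[ect > 1 & ect < nrow(ecg$beats)]
  spans <- ecg$beats$time[ect + 1] - ecg$beats$time[ect - 1]
  expect_lt(max(abs(spans - 2.0)), 1e-9)
  # ectopic R amplitude reduced
  ire <- round(ecg$beats$time[ect] * ecg$fs) + 1
  inorm <- round(ecg$beats$time[which(ecg$beats$class == "normal")] * ecg$fs) + 1
  inorm <- inorm[inorm > 0 & inorm <= length(ecg$samples)]
  expect_lt(mean(ecg$samples[ire]), 0.85 * mean(ecg$samples[inorm]))
})

test_that("generator rejects invalid arguments", {
  expect_error(rhythm_spec(rr_mean = -1), "rr_mean")
  expect_error(rhythm_spec(rr_sd = -0.1), "rr_sd")
  spec <- rhythm_spec()
  expect_error(generate_ecg(spec, -5), "duration")
  expect_error(generate_ecg(spec, 1), "3 mean RR")
  expect_error(generate_ecg(spec, 10, fs = 50), "fs")
})

test_that("resampling to TR is exact for native rate and constants, accurate for sines", {
  spec <- rhythm_spec(seed = 5)
  ecg <- generate_ecg(spec, 10, fs = 400)
  same <- resample_to_tr(ecg, 1 / 400)
  expect_equal(same$samples, ecg$samples, tolerance = 1e-12)

  const <- ecg_record(rep(2.5, 1000), fs = 400)
  rc <- resample_to_tr(const, 0.0028)
  expect_true(all(abs(rc$samples - 2.5) < 1e-12))
  expect_equal(rc$fs, 1 / 0.0028)

  t <- (0:3999) / 400
  sine <- ecg_record(sin(2 * pi * t), fs = 400)
  rs <- resample_to_tr(sine, 0.0028)
  expect_lt(max(abs(rs$samples - sin(2 * pi * ecg_times(rs)))), 1e-3)

  expect_error(resample_to_tr(ecg, 20), "duration")
  expect_error(resample_to_tr(ecg, -1), "tr")
})

test_that("ECG CSV round-trips and rejects malformed files", {
  spec <- rhythm_spec(seed = 9, rr_sd = 0.03)
  ecg <- generate_ecg(spec, 5, fs = 100)
  ecg <- ecg_record(ecg$samples[1:100], fs = 100)
  path <- withr::local_tempfile(fileext = ".csv")
  write_ecg_csv(ecg, path)
  back <- read_ecg_csv(path)
  expect_lt(max(abs(back$samples - ecg$samples)), 1e-9)
  expect_equal(back$fs, ecg$fs, tolerance = 1e-6)

  shuffled <- withr::local_tempfile(fileext = ".csv")
  df <- utils::read.csv(path)
  set.seed(1)
  utils::write.csv(df[sample(nrow(df)), ], shuffled, row.names = FALSE)
  expect_error(read_ecg_csv(shuffled), "increasing")

  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines(character(0), empty)
  expect_error(read_ecg_csv(empty), "malformed")

  jittered <- withr::local_tempfile(fileext = ".csv")
  df2 <- utils::read.csv(path)
  df2$time_s[50] <- df2$time_s[50] + 0.002
  utils::write.csv(df2, jittered, row.names = FALSE)
  expect_error(read_ecg_csv(jittered), "spacing|increasing")
})
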