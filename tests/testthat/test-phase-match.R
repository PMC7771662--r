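test_that("correlation trace matches a brute-force Pearson scan", {
  set.seed(21)
  history <- sinus_ecg(duration = 8, rr_sd = 0.03, seed = 21)
  w <- history$samples[1201:1320]
  ct <- cross_correlate(w, history)
  oracle <- pearson_scan_oracle(w, history$samples)
  expect_lt(max(abs(ct$trace - oracle)), 1e-10)
  expect_length(ct$trace, length(history$samples) - length(w) + 1)
  expect_true(all(ct$trace <= 1 + 1e-12 & ct$trace >= -1 - 1e-12))
})

test_that("verbatim and negated slices score +1 / -1 at their position", {
  set.seed(2)
  h <- cumsum(rnorm(2000))
  w <- h[501:620]
  ct <- cross_correlate(w, h)
  expect_equal(ct$trace[501], 1.0, tolerance = 1e-12)
  ctn <- cross_correlate(-w, h)
  expect_equal(ctn$trace[501], -1.0, tolerance = 1e-12)
})

test_that("periodic history yields correlation maxima spaced one period apart", {
  ecg <- generate_ecg(rhythm_spec(rr_mean = 1, rr_sd = 0, noise_sd = 0, seed = 1),
                      12, fs = 400)
  w <- ecg$samples[3001:3120]  # one QRS-T stretch
  ct <- cross_correlate(w, ecg)
  m <- find_phase_matches(ct, n_matches = 8, min_separation = 0.5,
                          min_score = 0.95)
  pos <- sort(m$positions)
  expect_true(all(abs(diff(pos) %% 400) <= 1 | abs(diff(pos) %% 400 - 400) <= 1))
})

test_that("zero-variance inputs are handled per contract", {
  expect_error(cross_correlate(rep(1, 50), rnorm(500)), "zero-variance")
  h <- c(rep(0, 200), rnorm(300))
  ct <- cross_correlate(rnorm(50), h)
  expect_equal(ct$trace[1], 0)      # flat segment scores 0
  expect_true(1 %in% ct$flagged)
})

test_that("peak selection is greedy by score with an exclusion zone", {
  tr <- numeric(1000)
  tr[200] <- 0.95; tr[500] <- 0.90; tr[800] <- 0.85
  m <- find_phase_matches(tr, n_matches = 2, min_separation = 50, min_score = 0.8)
  expect_equal(m$positions, c(200, 500))
  expect_equal(m$peak_scores, c(0.95, 0.90))
  expect_true(all(diff(m$peak_scores) <= 0))

  # two peaks 0.1 s apart at fs = 1 kHz with min_separation 0.3 s
  tr2 <- numeric(2000)
  tr2[1000] <- 0.92; tr2[1100] <- 0.99
  ct <- structure(list(trace = tr2, fs = 1000, t0 = 0, window = 1,
                       flagged = integer(0)), class = "corr_trace")
  m2 <- find_phase_matches(ct, n_matches = 5, min_separation = 0.3,
                           min_score = 0.8)
  expect_equal(m2$positions, 1100)

  m0 <- find_phase_matches(tr, n_matches = 0)
  expect_length(m0$peak_times, 0)
  expect_error(find_phase_matches(tr, 2, min_separation = -1), "positive")
})

test_that("matches on sinus ECG align with true beats to within 2 samples", {
  ecg <- sinus_ecg(duration = 30, rr_sd = 0, seed = 13, noise_sd = 0.01)
  fs <- ecg$fs
  now_i <- 10000
  w <- ecg$samples[(now_i - 119):now_i]
  ct <- cross_correlate(w, ecg_record(ecg$samples[1:(now_i - 200)], fs))
  m <- find_phase_matches(ct, n_matches = 3, min_separation = 0.3,
                          min_score = 0.8)
  expect_length(m$peak_times, 3)
  # with a strictly regular rhythm matched ends sit whole periods before now
  offs <- ((now_i - 1) / fs - m$peak_times) %% 1.0
  expect_true(all(pmin(offs, 1 - offs) <= 2 / fs + 1e-9))
})

test_that("arrhythmic windows preferentially match prior ectopic beats", {
  spec <- rhythm_spec(rr_mean = 1.0, rr_sd = 0.04, p_ectopic = 0.25, seed = 11)
  ecg <- generate_ecg(spec, 240, fs = 400)
  b <- ecg$beats
  fs <- ecg$fs
  win <- round(0.3 * fs)
  cls_of <- function(t) b$class[which.min(abs(b$time - t))]
  ect <- b$time[b$class == "ectopic"]
  ect <- ect[ect > 20 & ect < 235]
  matched <- unlist(lapply(ect, function(tb) {
    iend <- round((tb + 0.05) * fs)
    recent <- ecg$samples[(iend - win + 1):iend]
    hist <- ecg_record(ecg$samples[1:(iend - win)], fs)
    m <- find_phase_matches(cross_correlate(recent, hist), n_matches = 3,
                            min_separation = 0.3, min_score = 0.8)
    if (!length(m$peak_times)) return(NULL)
    vapply(m$peak_times - 0.05, cls_of, "")
  }))
  expect_gt(mean(matched == "ectopic"), 0.8)
})

test_that("per-step correlation cost scales linearly with history length", {
  w <- rnorm(120)
  h1 <- rnorm(20000)
  h8 <- rnorm(160000)
  t1 <- system.time(for (r in 1:5) cross_correlate(w, h1))[3]
  t8 <- system.time(for (r in 1:5) cross_correlate(w, h8))[3]
  # 8x the history must not cost more than ~5x the linear prediction
  expect_lt(t8, 40 * max(t1, 0.005))
})

test_that("the tracked per-step series carries matches across flat windows", {
  ecg <- sinus_ecg(duration = 30, seed = 7)
  scheme <- segmentation_scheme(5, 6)
  ecg_tr <- resample_to_tr(ecg, scheme$tr)
  ms <- phase_match_series(ecg_tr, scheme)
  n <- nrow(ms$idx)
  raw_full <- rowSums(!is.na(ms$raw_idx)) == 4
  trk_full <- rowSums(!is.na(ms$idx)) == 4
  first <- which(raw_full)[1]
  expect_true(all(trk_full[first:n]))       # never loses a full match set
  expect_false(all(raw_full[first:n]))      # while raw scans do have holes
  # matched ends always predate the step by the exclusion zone
  lags <- (seq_len(n) - ms$idx[, 1])
  expect_true(all(lags[!is.na(lags)] >= ms$excl))
})
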