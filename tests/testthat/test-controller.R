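test_that("frame-size rule reproduces the published (N_theta, N_q, N_s) triples", {
  triples <- rbind(
    # simulation study schemes
    c(27, 1, 54), c(27, 2, 18), c(27, 5, 6),
    c(45, 1, 90), c(45, 2, 30), c(45, 5, 10), c(45, 8, 6),
    c(75, 1, 150), c(75, 2, 50), c(75, 8, 10),
    # in-vivo schemes
    c(27, 5, 6), c(45, 5, 10), c(45, 8, 6), c(75, 8, 10))
  for (r in seq_len(nrow(triples))) {
    sch <- segmentation_scheme(triples[r, 2], triples[r, 3])
    expect_identical(sch$n_views, as.integer(triples[r, 1]))
  }
  expect_error(segmentation_scheme(0, 6), "n_shots")
  expect_error(segmentation_scheme(2, 5), "even")
  expect_error(segmentation_scheme(2, 6, tr = 0), "tr")
})

test_that("golden increments advance by 111.25 degrees mod 180", {
  expect_equal(golden_next(0), 111.25)
  expect_equal(golden_next(111.25), 42.5)
  th <- 0
  angs <- numeric(144)
  for (i in 1:144) { angs[i] <- th; th <- golden_next(th) }
  expect_lt(max(angular_gaps(angs)), 2.6)   # 144 views cover densely
  expect_error(golden_next(180), "\\[0, 180\\)")
})

test_that("random angles are uniform on [0, 180) and seed-deterministic", {
  set.seed(99)
  x <- random_next(1e5)
  expect_true(all(x >= 0 & x < 180))
  ks <- suppressWarnings(stats::ks.test(x, "punif", 0, 180))
  expect_lt(unname(ks$statistic), 0.01)
  set.seed(99)
  expect_identical(random_next(1e5), x)
})

test_that("angular gaps include the wrap gap and sum to 180 exactly", {
  expect_equal(as.numeric(angular_gaps(c(0, 90))), c(90, 90))
  expect_equal(as.numeric(angular_gaps(c(0, 45, 90))), c(45, 45, 90))
  expect_equal(as.numeric(angular_gaps(c(10, 20))), c(10, 170))
  expect_error(angular_gaps(numeric(0)), "non-empty")
  set.seed(4)
  for (rep in 1:50) {
    g <- angular_gaps(runif(sample(2:80, 1), 0, 180))
    expect_lt(abs(sum(g) - 180), 1e-9)
  }
})

test_that("bisection picks the largest gap with the stated tie-break", {
  expect_equal(next_angle_bisect(c(0, 90)), 45)    # tie -> smallest start
  expect_equal(next_angle_bisect(c(0, 45, 90)), 135)
  expect_equal(next_angle_bisect(c(10, 20)), 105)  # wrap gap 20 -> 190
  expect_error(next_angle_bisect(numeric(0)), "non-empty")
})

test_that("frame collation implements matched windows plus the half-shot", {
  tr <- 2.8e-3
  mk_log <- function(n) {
    structure(data.frame(index = 0:(n - 1), time_s = (0:(n - 1)) * tr,
                         angle_deg = golden_sequence(n), mode = "golden",
                         phase = "active", stringsAsFactors = FALSE),
              class = c("view_log", "data.frame"))
  }
  log <- mk_log(6000)
  # N_q = 5, N_s = 6: 4 matched windows of 6 plus 3 recent = 27
  sch <- segmentation_scheme(5, 6, tr)
  now <- 5000 * tr
  matches <- now - c(1, 2, 3, 4) * 0.9
  fv <- collate_frame_views(log, matches, sch, now = now)
  expect_length(fv$angles, 27)
  expect_true(all(fv$times < now))

  # N_q = 1, N_s = 54: the 27 most recent views, no matches needed
  sch1 <- segmentation_scheme(1, 54, tr)
  fv1 <- collate_frame_views(log, numeric(0), sch1, now = now)
  expect_length(fv1$angles, 27)
  expect_equal(fv1$times, ((5000 - 27):(5000 - 1)) * tr)

  # N_q = 8, N_s = 10: 7 * 10 + 5 = 75
  sch8 <- segmentation_scheme(8, 10, tr)
  m8 <- now - (1:7) * 0.9
  fv8 <- collate_frame_views(log, m8, sch8, now = now)
  expect_length(fv8$angles, 75)

  # overlapping matched windows deduplicate by time stamp
  fvdup <- collate_frame_views(log, rep(matches[1], 4), sch, now = now)
  expect_lte(length(fvdup$angles), 27)
  expect_false(any(duplicated(fvdup$times)))
})

test_that("open-loop schedules follow their definitions", {
  ecg <- sinus_ecg(duration = 10, seed = 2)
  sch <- segmentation_scheme(1, 54)
  lg <- run_acquisition(ecg, sch, "golden")
  n <- nrow(lg)
  expect_equal(lg$angle_deg, ((0:(n - 1)) * 111.25) %% 180, tolerance = 1e-12)
  le <- run_acquisition(ecg, sch, "equispaced")
  expect_equal(le$angle_deg, ((0:(n - 1)) * (180 / 27)) %% 180,
               tolerance = 1e-12)
  us <- uniformity_series(le, sch)
  expect_equal(us$mean, 1, tolerance = 1e-12)
  expect_lt(us$sd, 1e-12)
})

test_that("acquisitions are pure functions of (ecg, scheme, mode, config, seed)", {
  ecg <- sinus_ecg(duration = 12, seed = 3)
  sch <- segmentation_scheme(2, 18)
  a <- run_acquisition(ecg, sch, "arks", seed = 5)
  b <- run_acquisition(ecg, sch, "arks", seed = 5)
  expect_identical(a$angle_deg, b$angle_deg)
  expect_identical(a$phase, b$phase)
  r1 <- run_acquisition(ecg, sch, "random", seed = 5)
  r2 <- run_acquisition(ecg, sch, "random", seed = 5)
  expect_identical(r1$angle_deg, r2$angle_deg)
  expect_false(identical(r1$angle_deg,
                         run_acquisition(ecg, sch, "random", seed = 6)$angle_deg))
})

test_that("single-shot closed loop bisects its own trailing frame", {
  ecg <- sinus_ecg(duration = 15, seed = 4)
  sch <- segmentation_scheme(1, 54)
  lg <- run_acquisition(ecg, sch, "arks")
  expect_true(all(lg$angle_deg >= 0 & lg$angle_deg < 180))
  act <- which(lg$phase == "active")
  for (i in act[seq(1, length(act), length.out = 200)]) {
    frame <- lg$angle_deg[(i - 27):(i - 1)]
    expect_equal(lg$angle_deg[i], next_angle_bisect(frame), tolerance = 1e-9)
  }
  # training -> active transition is monotone
  ph <- factor(lg$phase, levels = c("training_A", "training_B", "active"))
  expect_true(all(diff(as.integer(ph)) >= 0))
})

test_that("the closed loop abandons the golden pattern after activation", {
  ecg <- sinus_ecg(duration = 15, seed = 8)
  sch <- segmentation_scheme(1, 54)
  lg <- run_acquisition(ecg, sch, "arks")
  a0 <- attr(lg, "active_start")
  within_1s <- a0:(a0 + round(1 / sch$tr))
  incr <- (diff(lg$angle_deg[within_1s])) %% 180
  expect_gt(max(abs(incr - 111.25)), 1)
})

test_that("multi-shot frames ramp up and reach N_theta in steady state", {
  ecg <- sinus_ecg(duration = 20, seed = 6)
  sch <- segmentation_scheme(5, 6)
  lg <- run_acquisition(ecg, sch, "arks")
  ms <- attr(lg, "matches")
  a0 <- attr(lg, "active_start")
  sizes <- vapply(seq(a0, nrow(lg), by = 97), function(i)
    length(arksim:::cpp_collate_one(i, ms$idx, sch$n_segments, sch$n_shots)),
    0L)
  expect_true(all(sizes == sch$n_views))
  # during training the collatable frame is never larger than N_theta
  pre <- vapply(seq(30, a0 - 1, by = 53), function(i)
    length(arksim:::cpp_collate_one(i, ms$idx, sch$n_segments, sch$n_shots)),
    0L)
  expect_true(all(pre <= sch$n_views))
})

test_that("view logs round-trip through CSV and reject malformed input", {
  ecg <- sinus_ecg(duration = 5, seed = 2)
  sch <- segmentation_scheme(1, 54)
  lg <- run_acquisition(ecg, sch, "golden")
  path <- withr::local_tempfile(fileext = ".csv")
  write_viewlog_csv(lg, path, comment = "arksim test")
  back <- read_viewlog_csv(path)
  expect_equal(back$angle_deg, round(lg$angle_deg, 6))
  expect_equal(back$time_s, round(lg$time_s, 6))

  bad <- withr::local_tempfile(fileext = ".csv")
  lines <- readLines(path)
  lines[10] <- sub("^([0-9]+,[0-9.]+,)[0-9.]+", "\\1181.0", lines[10])
  writeLines(lines, bad)
  expect_error(read_viewlog_csv(bad), "line")
})
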