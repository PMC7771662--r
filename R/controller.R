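#' Segmentation scheme of a segmented cine acquisition
#'
#' `n_shots` (N_q) heartbeats each contribute `n_segments` (N_s) radial
#' views to one image frame. Because the closed loop can only use the half
#' of the current shot that has already happened, the per-frame view count
#' is `N_theta = N_s * (N_q - 1) + N_s / 2`.
#'
#' @param n_shots number of shots N_q (>= 1).
#' @param n_segments views per shot N_s (even, >= 2).
#' @param tr repetition time, seconds.
#' @return an object of class `segmentation_scheme` with derived `n_views`.
#' @export
segmentation_scheme <- function(n_shots, n_segments, tr = 2.8e-3) {
  if (n_shots < 1) stop("n_shots must be >= 1", call. = FALSE)
  if (n_segments < 2 || n_segments %% 2 != 0)
    stop("n_segments must be even and >= 2", call. = FALSE)
  if (tr <= 0) stop("tr must be positive", call. = FALSE)
  structure(list(n_shots = as.integer(n_shots),
                 n_segments = as.integer(n_segments),
                 n_views = as.integer(n_segments * (n_shots - 1) + n_segments / 2),
                 tr = tr),
            class = "segmentation_scheme")
}

#' @export
print.segmentation_scheme <- function(x, ...) {
  cat(sprintf("<segmentation_scheme> N_q=%d shots x N_s=%d segments -> N_theta=%d views/frame, TR=%.4g s\n",
              x$n_shots, x$n_segments, x$n_views, x$tr))
  invisible(x)
}

#' Open-loop angle schedules and gap geometry
#'
#' `golden_next` advances a view angle by the golden angle 111.25 degrees
#' (mod 180); `random_next` draws i.i.d. uniform angles on `[0, 180)`;
#' `angular_gaps` returns the adjacent-angle gaps of a frame including the
#' wrap gap (`180 - max + min`), which sum to exactly 180;
#' `next_angle_bisect` returns the midpoint of the largest gap, ties broken
#' by the gap with the smallest start angle.
#'
#' @param theta view angle(s) in degrees, each in `[0, 180)`.
#' @param n number of random draws.
#' @param angles numeric vector of view angles in `[0, 180)`.
#' @return `golden_next`/`random_next`/`next_angle_bisect`: angles in
#'   degrees; `angular_gaps`: the gaps (same length as `angles`), with the
#'   sorted angles attached as attribute `starts`.
#' @export
golden_next <- function(theta) {
  if (any(theta < 0 | theta >= 180)) stop("theta must be in [0, 180)", call. = FALSE)
  (theta + 111.25) %% 180
}

#' @rdname golden_next
#' @export
random_next <- function(n = 1) runif(n, 0, 180)

#' @rdname golden_next
#' @export
angular_gaps <- function(angles) {
  if (length(angles) == 0) stop("angles must be non-empty", call. = FALSE)
  if (any(angles < 0 | angles >= 180)) stop("angles must be in [0, 180)", call. = FALSE)
  s <- sort(angles)
  n <- length(s)
  g <- if (n == 1) 180 else c(diff(s), 180 - s[n] + s[1])
  attr(g, "starts") <- s
  g
}

#' @rdname golden_next
#' @export
next_angle_bisect <- function(angles) {
  g <- angular_gaps(angles)
  s <- attr(g, "starts")
  i <- which.max(g)  # first maximum = smallest start angle on ties
  (s[i] + g[i] / 2) %% 180
}

#' Collate the views of one image frame
#'
#' For each matched time `t_m` the views with time stamps in
#' `[t_m - N_s*tr/2, t_m + N_s*tr/2)` are included, plus the `N_s/2` most
#' recent views (the half of the current shot that has happened),
#' deduplicated by time stamp.
#'
#' @param log a `view_log` (see [run_acquisition()]).
#' @param matches a `match_result`, or a numeric vector of matched times in
#'   seconds.
#' @param scheme a [segmentation_scheme()].
#' @param now current time, seconds (defaults to one TR past the last view).
#' @return an object of class `frame_views`: `angles`, `times`,
#'   `frame_time`.
#' @export
collate_frame_views <- function(log, matches, scheme, now = NULL) {
  if (nrow(log) == 0) stop("log must be non-empty", call. = FALSE)
  stopifnot(inherits(scheme, "segmentation_scheme"))
  tm <- if (inherits(matches, "match_result")) matches$peak_times else as.numeric(matches)
  if (is.null(now)) now <- log$time_s[nrow(log)] + scheme$tr
  keep <- rep(FALSE, nrow(log))
  past <- log$time_s < now
  for (t_m in tm) {
    # window of exactly n_segments TR slots centred on the matched time;
    # the epsilon keeps grid-aligned boundaries half-open
    u <- (log$time_s - t_m) / scheme$tr + scheme$n_segments / 2
    keep <- keep | (u >= -1e-6 & u < scheme$n_segments - 1e-6 & past)
  }
  recent <- which(past)
  recent <- tail(recent, scheme$n_segments / 2)
  keep[recent] <- TRUE
  sel <- which(keep)
  structure(list(angles = log$angle_deg[sel], times = log$time_s[sel],
                 frame_time = now),
            class = "frame_views")
}

#' @export
print.frame_views <- function(x, ...) {
  cat(sprintf("<frame_views> %d views at t=%.3f s\n", length(x$angles), x$frame_time))
  invisible(x)
}

#' Run a full acquisition on an ECG
#'
#' One view per TR for the whole ECG duration. In `arks` mode the
#' controller emits golden-angle increments during training (training A
#' while the correlation buffer fills, training B until `n_shots - 1`
#' matches at `min_score` are available; single-shot schemes activate as
#' soon as a full frame of views exists) and then, each TR: match the
#' trailing ECG window against the history, collate the frame from the
#' matched shots plus the current half-shot, and bisect the frame's largest
#' angular gap. `golden`, `random` and `equispaced` are open-loop
#' schedules; `equispaced` repeats `Delta theta = 180 / n_views`.
#'
#' @param ecg an [ecg_record()] (resampled internally to the TR grid).
#' @param scheme a [segmentation_scheme()].
#' @param mode one of `"arks"`, `"golden"`, `"random"`, `"equispaced"`.
#' @param match a [match_config()].
#' @param seed integer seed for the run's RNG (random mode).
#' @param theta0 golden-angle seed angle, degrees.
#' @param train_s duration of training A, seconds.
#' @param matches optional precomputed [phase_match_series()] for this ECG
#'   and scheme (avoids rescanning when several runs share one ECG).
#' @return a `view_log`: data frame with columns `index`, `time_s`,
#'   `angle_deg`, `mode`, `phase`, plus attributes `scheme`, `matches`
#'   (the phase-match series, `arks` multi-shot only) and `active_start`.
#' @export
run_acquisition <- function(ecg, scheme, mode = c("arks", "golden", "random", "equispaced"),
                            match = match_config(), seed = 1L, theta0 = 0,
                            train_s = 2, matches = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(ecg, "ecg_record"), inherits(scheme, "segmentation_scheme"))
  ecg_tr <- if (abs(ecg$fs - 1 / scheme$tr) < 1e-9) ecg else resample_to_tr(ecg, scheme$tr)
  n <- length(ecg_tr$samples)
  if (ecg_duration(ecg_tr) <= train_s)
    stop("ECG too short for the training period", call. = FALSE)

  train_a <- round(train_s / scheme$tr)
  phase_lab <- c("training_A", "training_B", "active")
  ms <- matches
  if (mode == "arks") {
    if (scheme$n_shots > 1) {
      if (is.null(ms)) ms <- phase_match_series(ecg_tr, scheme, match)
      midx <- ms$idx
    } else {
      midx <- matrix(NA_integer_, n, 1)
    }
    res <- cpp_run_arks(n, scheme$n_shots, scheme$n_segments, train_a,
                        theta0, midx)
    ang <- res$angle
    ph <- phase_lab[res$phase + 1]
    active_start <- res$active_start
  } else {
    idx0 <- seq_len(n) - 1
    ang <- switch(mode,
      golden = (theta0 + idx0 * 111.25) %% 180,
      equispaced = (theta0 + idx0 * (180 / scheme$n_views)) %% 180,
      random = with_seed(seed, random_next(n)))
    ph <- rep("active", n)
    active_start <- 1L
  }
  log <- data.frame(index = seq_len(n) - 1L,
                    time_s = ecg_tr$t0 + (seq_len(n) - 1) * scheme$tr,
                    angle_deg = ang, mode = mode, phase = ph,
                    stringsAsFactors = FALSE)
  class(log) <- c("view_log", "data.frame")
  attr(log, "scheme") <- scheme
  attr(log, "matches") <- ms
  attr(log, "active_start") <- active_start
  attr(log, "seed") <- seed
  log
}

#' Read / write a view-angle log as CSV
#'
#' Header `index,time_s,angle_deg,mode,phase`, one row per TR, angles with
#' 6 decimal digits. An optional leading comment line carries the config
#' hash and seed.
#'
#' @param log a `view_log`.
#' @param path file path.
#' @param comment optional single comment line (written prefixed with `#`).
#' @return `read_viewlog_csv`: a `view_log`; `write_viewlog_csv`: `path`,
#'   invisibly.
#' @export
write_viewlog_csv <- function(log, path, comment = NULL) {
  lines <- c(if (!is.null(comment)) paste0("# ", comment),
             "index,time_s,angle_deg,mode,phase",
             sprintf("%d,%.6f,%.6f,%s,%s", log$index, log$time_s,
                     log$angle_deg, log$mode, log$phase))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_viewlog_csv
#' @export
read_viewlog_csv <- function(path) {
  lines <- readLines(path)
  skip <- sum(startsWith(head(lines, 5), "#"))
  df <- tryCatch(read.csv(path, skip = skip, stringsAsFactors = FALSE),
                 error = function(e)
                   stop("malformed view log: ", conditionMessage(e), call. = FALSE))
  need <- c("index", "time_s", "angle_deg", "mode", "phase")
  if (!all(need %in% names(df)))
    stop("malformed view log: missing columns", call. = FALSE)
  bad <- which(!is.finite(df$angle_deg) | df$angle_deg < 0 | df$angle_deg >= 180)
  if (length(bad))
    stop(sprintf("malformed view log: angle out of [0,180) at line %d",
                 bad[1] + 1 + skip), call. = FALSE)
  if (nrow(df) > 1) {
    dt <- diff(df$time_s)
    if (any(dt <= 0))
      stop("malformed view log: time stamps must be strictly increasing",
           call. = FALSE)
    if ((max(dt) - min(dt)) > 1e-9 + 1e-6 * mean(dt))
      stop("malformed view log: non-uniform TR spacing", call. = FALSE)
  }
  class(df) <- c("view_log", "data.frame")
  df
}
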