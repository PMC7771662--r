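#' Radial acquisition geometry
#'
#' @param n_readout samples per projection N_r (even, >= 2).
#' @param fov field of view in meters; `dk = 1/fov`.
#' @param dk radial k-space sample spacing in 1/m (alternative to `fov`).
#' @param grid_size Cartesian grid size for PSF / reconstruction (two-fold
#'   oversampled relative to `n_readout` by default).
#' @return an object of class `radial_geometry` with derived
#'   `k_max = n_readout * dk / 2`.
#' @export
radial_geometry <- function(n_readout = 128, fov = 0.34, dk = NULL,
                            grid_size = 2 * n_readout) {
  if (n_readout < 2 || n_readout %% 2 != 0)
    stop("n_readout must be even and >= 2", call. = FALSE)
  if (is.null(dk)) dk <- 1 / fov else fov <- 1 / dk
  if (dk <= 0) stop("dk must be positive", call. = FALSE)
  if (grid_size < 2 * n_readout)
    stop("grid_size must be at least 2 * n_readout", call. = FALSE)
  structure(list(n_readout = as.integer(n_readout), dk = dk, fov = fov,
                 k_max = n_readout * dk / 2,
                 grid_size = as.integer(grid_size)),
            class = "radial_geometry")
}

#' @export
print.radial_geometry <- function(x, ...) {
  cat(sprintf("<radial_geometry> N_r=%d, dk=%.3f 1/m (FOV %.3g m), grid %d^2\n",
              x$n_readout, x$dk, x$fov, x$grid_size))
  invisible(x)
}

#' Nyquist view count and aliasing-free field of view
#'
#' `nyquist_views` is the number of projections needed to satisfy the
#' radial Nyquist criterion, `ceil(N_r * pi / 2)` (a lower bound, hence the
#' ceiling). With fewer views the aliasing-free diameter shrinks to
#' `reduced_fov = n_views / (2 * pi * N_r) * fov`.
#'
#' @param geom a [radial_geometry()], or a plain readout length.
#' @param n_views number of projections actually acquired.
#' @return `nyquist_views`: integer count; `reduced_fov`: diameter in
#'   meters.
#' @export
nyquist_views <- function(geom) {
  nr <- if (inherits(geom, "radial_geometry")) geom$n_readout else geom
  if (any(nr < 1)) stop("n_readout must be >= 1", call. = FALSE)
  as.integer(ceiling(nr * pi / 2))
}

#' @rdname nyquist_views
#' @export
reduced_fov <- function(n_views, geom) {
  stopifnot(inherits(geom, "radial_geometry"))
  if (n_views < 1) stop("n_views must be >= 1", call. = FALSE)
  n_views / (2 * pi * geom$n_readout) / geom$dk
}

#' Angular sampling uniformity of one frame
#'
#' The `N - 1` adjacent differences of the sorted view angles are sorted
#' ascending; their cumulative sums are summed and compared with the
#' equal-gap ideal in which all views are separated by `180 / N` degrees
#' (the delta-distribution ideal):
#' `U = sum_k CS(k) / sum_k CS_ideal(k)`, `CS_ideal(k) = k * 180 / N`,
#' denominator `90 * (N - 1)`. `U = 1` exactly for an equispaced frame;
#' clustered frames score lower.
#'
#' @param angles numeric vector of view angles in degrees (>= 2, each in
#'   `[0, 180)`), or a `frame_views`.
#' @return uniformity U, dimensionless.
#' @export
uniformity <- function(angles) {
  if (inherits(angles, "frame_views")) angles <- angles$angles
  if (length(angles) < 2) stop("need at least 2 angles", call. = FALSE)
  if (any(angles < 0 | angles >= 180)) stop("angles must be in [0, 180)", call. = FALSE)
  n <- length(angles)
  g <- sort(diff(sort(angles)))
  sum(cumsum(g)) / (90 * (n - 1))
}

#' Per-frame uniformity over an acquisition
#'
#' Evaluates U for every frame past training with a sliding window of one
#' view. Single-shot schemes use the trailing `n_views` most recent views;
#' multi-shot schemes collate each frame from the ECG-matched shots plus
#' the current half-shot (the same collation the closed-loop controller
#' uses, so golden/random logs are analysed on identical frames).
#'
#' @param log a `view_log` from [run_acquisition()], or a plain numeric
#'   vector of angles.
#' @param scheme a [segmentation_scheme()] (taken from the log if absent).
#' @param matches a phase-match series from [phase_match_series()] for
#'   multi-shot frame collation (taken from the log if absent).
#' @param from first 1-based step to evaluate (defaults to the log's
#'   `active_start`, or the first full frame).
#' @param width frame width when `log` is a plain angle vector.
#' @return an object of class `uniformity_result`: per-frame `u`, `mean`,
#'   `sd`, `n_frames`, `steps`.
#' @export
uniformity_series <- function(log, scheme = NULL, matches = NULL, from = NULL,
                              width = NULL) {
  if (is.numeric(log)) {
    if (is.null(width)) stop("width required for a plain angle vector", call. = FALSE)
    u <- cpp_sliding_uniformity(log, as.integer(width))
    steps <- seq.int(width, length(log))
  } else {
    if (is.null(scheme)) scheme <- attr(log, "scheme")
    stopifnot(inherits(scheme, "segmentation_scheme"))
    ang <- log$angle_deg
    n <- length(ang)
    if (is.null(from)) {
      from <- attr(log, "active_start")
      if (is.null(from) || is.na(from)) from <- scheme$n_views + 1L
    }
    if (n < scheme$n_views)
      stop("log too short for a full frame", call. = FALSE)
    if (scheme$n_shots == 1) {
      # frame at step i is the trailing window of n_views ending at i
      steps <- seq.int(min(max(from, scheme$n_views), n), n)
      u0 <- cpp_sliding_uniformity(ang, scheme$n_views)
      u <- u0[steps - scheme$n_views + 1L]
    } else {
      if (is.null(matches)) matches <- attr(log, "matches")
      if (is.null(matches))
        stop("multi-shot analysis needs a phase-match series", call. = FALSE)
      steps <- seq.int(max(from, scheme$n_segments + 1L), n)
      u <- cpp_collated_uniformity(ang, matches$idx, scheme$n_segments,
                                   scheme$n_shots, steps)
    }
  }
  ok <- is.finite(u)
  structure(list(u = u, steps = steps, mean = mean(u[ok]), sd = sd(u[ok]),
                 n_frames = sum(ok)),
            class = "uniformity_result")
}

#' @export
print.uniformity_result <- function(x, ...) {
  cat(sprintf("<uniformity_result> %d frames: mean U = %.1f%%, sd = %.2f\n",
              x$n_frames, 100 * x$mean, 100 * x$sd))
  invisible(x)
}

#' Compare trajectories acquired on the same ECG
#'
#' Paired per-scheme summary: mean and sd of per-frame uniformity and the
#' PSF main-lobe signal ratio for each log, plus relative improvements of
#' every mode over the golden-angle log, `(mode - golden) / golden * 100`.
#'
#' @param logs named list of `view_log`s (same ECG and scheme; names are
#'   the modes).
#' @param scheme a [segmentation_scheme()].
#' @param geom a [radial_geometry()] for the PSF, or NULL to skip PSF.
#' @param matches shared phase-match series for multi-shot collation.
#' @param from first step to evaluate for every log (paired frames).
#' @param psf_frames number of frames entering the averaged PSF.
#' @return an object of class `trajectory_report` (list of per-mode rows;
#'   `as.data.frame` gives the table).
#' @export
compare_trajectories <- function(logs, scheme, geom = NULL, matches = NULL,
                                 from = NULL, psf_frames = 200) {
  stopifnot(is.list(logs), length(logs) >= 1, inherits(scheme, "segmentation_scheme"))
  schemes <- lapply(logs, attr, "scheme")
  for (s in schemes) {
    if (is.null(s)) next
    if (s$n_shots != scheme$n_shots || s$n_segments != scheme$n_segments ||
        abs(s$tr - scheme$tr) > 1e-12)
      stop("logs were acquired under different schemes", call. = FALSE)
  }
  if (is.null(from)) {
    starts <- vapply(logs, function(l) {
      a <- attr(l, "active_start"); if (is.null(a) || is.na(a)) 1L else a
    }, 1L)
    from <- max(starts, scheme$n_views + 1L)
  }
  if (is.null(matches))
    for (l in logs) if (!is.null(attr(l, "matches"))) { matches <- attr(l, "matches"); break }
  rows <- lapply(names(logs), function(nm) {
    us <- uniformity_series(logs[[nm]], scheme, matches = matches, from = from)
    psf <- NA_real_
    if (!is.null(geom)) {
      fr <- frame_angle_list(logs[[nm]], scheme, matches = matches, from = from,
                             n_frames = psf_frames)
      pr <- psf_profile_and_ratio(psf_average(fr, geom), geom)
      psf <- pr$ratio
    }
    list(mode = nm, n_frames = us$n_frames,
         mean_uniformity_pct = 100 * us$mean, sd_uniformity_pct = 100 * us$sd,
         psf_ratio_pct = 100 * psf)
  })
  names(rows) <- names(logs)
  if ("golden" %in% names(rows)) {
    g <- rows$golden
    for (nm in names(rows)) {
      rows[[nm]]$rel_uniformity_vs_golden_pct <-
        (rows[[nm]]$mean_uniformity_pct - g$mean_uniformity_pct) /
          g$mean_uniformity_pct * 100
    }
  }
  structure(list(scheme = list(n_views = scheme$n_views, n_shots = scheme$n_shots,
                               n_segments = scheme$n_segments),
                 modes = rows),
            class = "trajectory_report")
}

#' @export
as.data.frame.trajectory_report <- function(x, ...) {
  do.call(rbind, lapply(x$modes, function(r)
    data.frame(r[!vapply(r, is.null, TRUE)], stringsAsFactors = FALSE)))
}

#' @export
print.trajectory_report <- function(x, ...) {
  cat(sprintf("<trajectory_report> N_theta=%d (N_q=%d x N_s=%d)\n",
              x$scheme$n_views, x$scheme$n_shots, x$scheme$n_segments))
  print(as.data.frame(x))
  invisible(x)
}

# evenly spaced sample of per-step frames as a list of angle vectors
frame_angle_list <- function(log, scheme, matches = NULL, from = NULL,
                             n_frames = 200) {
  ang <- log$angle_deg
  n <- length(ang)
  if (is.null(from)) {
    from <- attr(log, "active_start")
    if (is.null(from) || is.na(from)) from <- scheme$n_views + 1L
  }
  steps <- seq.int(min(max(from, scheme$n_views), n), n)
  if (length(steps) > n_frames)
    steps <- steps[round(seq(1, length(steps), length.out = n_frames))]
  if (scheme$n_shots == 1) {
    lapply(steps, function(i) ang[(i - scheme$n_views + 1L):i])
  } else {
    if (is.null(matches)) matches <- attr(log, "matches")
    if (is.null(matches))
      stop("multi-shot frames need a phase-match series", call. = FALSE)
    lapply(steps, function(i)
      ang[cpp_collate_one(i, matches$idx, scheme$n_segments, scheme$n_shots)])
  }
}
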