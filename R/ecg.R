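#' Uniformly sampled physiologic trace
#'
#' Container for a single-channel ECG-like signal: the controller's feedback
#' signal. Sample `i` (1-based) is located at time `t0 + (i-1)/fs`.
#'
#' @param samples numeric vector of amplitudes (arbitrary mV-like units).
#' @param fs sampling rate in Hz (> 0).
#' @param t0 start time in seconds.
#' @param beats optional data frame of ground-truth beat annotations
#'   (columns `time`, `class`) attached by [generate_ecg()].
#' @return an object of class `ecg_record`.
#' @export
ecg_record <- function(samples, fs, t0 = 0, beats = NULL) {
  if (!is.numeric(samples) || length(samples) == 0)
    stop("samples must be a non-empty numeric vector", call. = FALSE)
  if (!all(is.finite(samples)))
    stop("samples must all be finite", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0)
    stop("fs must be a single positive number", call. = FALSE)
  structure(list(samples = as.numeric(samples), fs = as.numeric(fs),
                 t0 = as.numeric(t0), beats = beats),
            class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record> %d samples @ %g Hz, %.2f s\n",
              length(x$samples), x$fs, ecg_duration(x)))
  invisible(x)
}

#' Duration and time stamps of an ECG record
#' @param ecg an [ecg_record()].
#' @return `ecg_duration`: length in seconds; `ecg_times`: per-sample times.
#' @export
ecg_duration <- function(ecg) length(ecg$samples) / ecg$fs

#' @rdname ecg_duration
#' @export
ecg_times <- function(ecg) ecg$t0 + (seq_along(ecg$samples) - 1) / ecg$fs

# default 5-Gaussian beat template (P, Q, R, S, T)
.wave_defaults <- list(
  amp    = c(P = 0.12, Q = -0.10, R = 1.00, S = -0.15, T = 0.30),
  sigma  = c(P = 0.025, Q = 0.010, R = 0.012, S = 0.010, T = 0.040),
  offset = c(P = -0.20, Q = -0.03, R = 0.00, S = 0.03, T = 0.25)
)

#' Rhythm specification for the synthetic ECG generator
#'
#' Parameterizes the stand-in for a recorded chest ECG: mean RR interval and
#' its beat-to-beat variability, an ectopy option (premature beat with
#' reduced R amplitude followed by a compensatory pause so that the two-beat
#' span equals `2 * rr_mean`), per-wave Gaussian morphology, measurement
#' noise and baseline wander.
#'
#' @param rr_mean mean RR interval, seconds (> 0).
#' @param rr_sd beat-to-beat RR standard deviation, seconds (>= 0); draws
#'   are truncated below at `0.3 * rr_mean` (refractoriness).
#' @param p_ectopic per-beat probability of a premature (ectopic) beat.
#' @param ectopic_rr_scale RR scale of the premature coupling interval.
#' @param wave_amp,wave_sigma,wave_offset named numeric vectors (P,Q,R,S,T):
#'   amplitudes, Gaussian widths (s) and offsets from the R peak (s).
#' @param noise_sd additive white Gaussian noise amplitude.
#' @param baseline_amp,baseline_freq sinusoidal baseline wander amplitude
#'   and frequency (Hz).
#' @param seed integer seed; the generated trace is a pure function of
#'   (spec, duration, fs).
#' @return an object of class `rhythm_spec`.
#' @export
rhythm_spec <- function(rr_mean = 1.0, rr_sd = 0.0, p_ectopic = 0.0,
                        ectopic_rr_scale = 0.6,
                        wave_amp = .wave_defaults$amp,
                        wave_sigma = .wave_defaults$sigma,
                        wave_offset = .wave_defaults$offset,
                        noise_sd = 0.02, baseline_amp = 0.0,
                        baseline_freq = 0.25, seed = 1L) {
  if (rr_mean <= 0) stop("rr_mean must be positive", call. = FALSE)
  if (rr_sd < 0) stop("rr_sd must be non-negative", call. = FALSE)
  if (p_ectopic < 0 || p_ectopic >= 1)
    stop("p_ectopic must be in [0, 1)", call. = FALSE)
  if (any(wave_sigma <= 0)) stop("wave widths must be positive", call. = FALSE)
  structure(list(rr_mean = rr_mean, rr_sd = rr_sd, p_ectopic = p_ectopic,
                 ectopic_rr_scale = ectopic_rr_scale, wave_amp = wave_amp,
                 wave_sigma = wave_sigma, wave_offset = wave_offset,
                 noise_sd = noise_sd, baseline_amp = baseline_amp,
                 baseline_freq = baseline_freq, seed = as.integer(seed)),
            class = "rhythm_spec")
}

#' @export
print.rhythm_spec <- function(x, ...) {
  cat(sprintf("<rhythm_spec> RR %.3f +- %.3f s, p_ectopic %.2f, seed %d\n",
              x$rr_mean, x$rr_sd, x$p_ectopic, x$seed))
  invisible(x)
}

#' Generate a synthetic ECG trace
#'
#' Sum-of-Gaussians beat model: each beat at time `t_b` contributes
#' `sum_w a_w * exp(-(t - t_b - o_w)^2 / (2 sigma_w^2))` over the five
#' P,Q,R,S,T waves. RR intervals are Normal(`rr_mean`, `rr_sd`) truncated at
#' `0.3 * rr_mean`; an ectopic beat is premature (`rr_mean *
#' ectopic_rr_scale`, R amplitude scaled by 0.7) and is followed by a
#' compensatory pause making the two-beat span `2 * rr_mean`. Beats are laid
#' down with one beat of margin on both ends so the interior of the trace is
#' free of edge effects.
#'
#' @param spec a [rhythm_spec()].
#' @param duration trace length in seconds (>= `3 * rr_mean`).
#' @param fs sampling rate in Hz (>= 100); 400 Hz emulates a clinical
#'   physiologic monitor.
#' @return an [ecg_record()] with ground-truth `beats` annotations.
#' @export
generate_ecg <- function(spec, duration, fs = 400) {
  stopifnot(inherits(spec, "rhythm_spec"))
  if (!is.numeric(duration) || duration <= 0)
    stop("duration must be positive", call. = FALSE)
  if (duration < 3 * spec$rr_mean)
    stop("duration must cover at least 3 mean RR intervals", call. = FALSE)
  if (!is.numeric(fs) || fs < 100)
    stop("fs must be at least 100 Hz", call. = FALSE)

  with_seed(spec$seed, {
    draw_rr <- function() {
      if (spec$rr_sd == 0) return(spec$rr_mean)
      repeat {
        r <- rnorm(1, spec$rr_mean, spec$rr_sd)
        if (r >= 0.3 * spec$rr_mean) return(r)
      }
    }
    tb <- -spec$rr_mean    # margin beat before t = 0
    beat_t <- numeric(0); beat_cls <- character(0); beat_amp <- numeric(0)
    pending_pause <- 0
    while (tb < duration + spec$rr_mean) {
      beat_t <- c(beat_t, tb);
      if (pending_pause > 0) {
        beat_cls <- c(beat_cls, "normal"); beat_amp <- c(beat_amp, 1)
        tb <- tb + pending_pause
        pending_pause <- 0
      } else if (spec$p_ectopic > 0 && runif(1) < spec$p_ectopic) {
        # this NEXT beat is premature; schedule its compensatory pause
        rr_short <- spec$rr_mean * spec$ectopic_rr_scale
        beat_cls <- c(beat_cls, "pre_ectopic"); beat_amp <- c(beat_amp, 1)
        tb <- tb + rr_short
        pending_pause <- 2 * spec$rr_mean - rr_short
      } else {
        beat_cls <- c(beat_cls, "normal"); beat_amp <- c(beat_amp, 1)
        tb <- tb + draw_rr()
      }
    }
    # the beat following a premature interval is the ectopic one
    ect <- which(beat_cls == "pre_ectopic") + 1
    ect <- ect[ect <= length(beat_t)]
    beat_cls[beat_cls == "pre_ectopic"] <- "normal"
    if (length(ect)) { beat_cls[ect] <- "ectopic"; beat_amp[ect] <- 0.7 }

    n <- round(duration * fs)
    t <- (seq_len(n) - 1) / fs
    sig <- numeric(n)
    margin <- max(abs(spec$wave_offset)) + 8 * max(spec$wave_sigma)
    for (b in seq_along(beat_t)) {
      lo <- max(1, ceiling((beat_t[b] - margin) * fs) + 1)
      hi <- min(n, floor((beat_t[b] + margin) * fs) + 1)
      if (lo > hi) next
      tt <- t[lo:hi] - beat_t[b]
      for (w in seq_along(spec$wave_amp)) {
        a <- spec$wave_amp[w]
        if (names(spec$wave_amp)[w] == "R") a <- a * beat_amp[b]
        sig[lo:hi] <- sig[lo:hi] +
          a * exp(-(tt - spec$wave_offset[w])^2 / (2 * spec$wave_sigma[w]^2))
      }
    }
    if (spec$baseline_amp != 0)
      sig <- sig + spec$baseline_amp * sin(2 * pi * spec$baseline_freq * t)
    if (spec$noise_sd > 0)
      sig <- sig + rnorm(n, 0, spec$noise_sd)

    keep <- beat_t >= 0 & beat_t < duration
    ecg_record(sig, fs, t0 = 0,
               beats = data.frame(time = beat_t[keep], class = beat_cls[keep],
                                  stringsAsFactors = FALSE))
  })
}

#' Resample an ECG record to the scanner repetition time
#'
#' Linear interpolation onto the grid `t0, t0 + tr, ...` covering the
#' original span; the result has sampling rate `1/tr` (one sample per
#' acquired radial view).
#'
#' @param ecg an [ecg_record()].
#' @param tr repetition time in seconds (> 0, shorter than the record).
#' @return an [ecg_record()] at rate `1/tr`.
#' @export
resample_to_tr <- function(ecg, tr) {
  stopifnot(inherits(ecg, "ecg_record"))
  if (!is.numeric(tr) || tr <= 0) stop("tr must be positive", call. = FALSE)
  dur <- ecg_duration(ecg)
  if (tr > dur) stop("tr exceeds the record duration", call. = FALSE)
  t_old <- ecg_times(ecg)
  n_new <- floor((t_old[length(t_old)] - ecg$t0) / tr) + 1
  t_new <- ecg$t0 + (seq_len(n_new) - 1) * tr
  y <- approx(t_old, ecg$samples, xout = t_new)$y
  ecg_record(y, fs = 1 / tr, t0 = ecg$t0, beats = ecg$beats)
}

#' Read / write an ECG record as CSV
#'
#' Two-column text format with header `time_s,amplitude`, one sample per
#' line, uniform spacing. Amplitudes are written with 9 decimal digits so a
#' write/read round trip reproduces the record to 1e-9.
#'
#' @param path file path.
#' @param ecg an [ecg_record()].
#' @return `read_ecg_csv`: an [ecg_record()]; `write_ecg_csv`: `path`,
#'   invisibly.
#' @export
read_ecg_csv <- function(path) {
  df <- tryCatch(read.csv(path), error = function(e)
    stop("malformed ECG CSV: ", conditionMessage(e), call. = FALSE))
  if (nrow(df) < 2 || ncol(df) < 2)
    stop("malformed ECG CSV: need >= 2 rows of time,amplitude", call. = FALSE)
  tm <- as.numeric(df[[1]]); y <- as.numeric(df[[2]])
  if (anyNA(tm) || anyNA(y))
    stop("malformed ECG CSV: non-numeric values", call. = FALSE)
  dt <- diff(tm)
  if (any(dt <= 0))
    stop("malformed ECG CSV: time column must be strictly increasing",
         call. = FALSE)
  if ((max(dt) - min(dt)) / mean(dt) > 1e-6)
    stop("malformed ECG CSV: non-uniform sample spacing", call. = FALSE)
  ecg_record(y, fs = 1 / mean(dt), t0 = tm[1])
}

#' @rdname read_ecg_csv
#' @export
write_ecg_csv <- function(ecg, path) {
  stopifnot(inherits(ecg, "ecg_record"))
  tm <- ecg_times(ecg)
  lines <- c("time_s,amplitude",
             sprintf("%.9f,%.9f", tm, ecg$samples))
  writeLines(lines, path)
  invisible(path)
}
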