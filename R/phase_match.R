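#' Match configuration for cardiac phase identification
#'
#' @param window_s length of the trailing ECG window that is correlated
#'   against the history, seconds. 300 ms spans the QRS-T complex.
#' @param min_score minimum Pearson correlation for an accepted match.
#' @param min_separation_s exclusion zone between accepted matches, seconds
#'   (refractory period).
#' @return a list of class `match_config`.
#' @export
match_config <- function(window_s = 0.3, min_score = 0.8,
                         min_separation_s = 0.3) {
  if (window_s <= 0 || min_separation_s <= 0)
    stop("window_s and min_separation_s must be positive", call. = FALSE)
  structure(list(window_s = window_s, min_score = min_score,
                 min_separation_s = min_separation_s),
            class = "match_config")
}

#' Normalized cross-correlation of a recent ECG window against history
#'
#' For every alignment position `p` of the window inside the history the
#' zero-mean, unit-norm (Pearson) correlation between the window and the
#' history segment `[p, p + W)` is returned; values lie in `[-1, 1]`.
#' Zero-variance history segments score 0 and are flagged; a zero-variance
#' window is a degenerate input.
#'
#' @param recent numeric vector or [ecg_record()]: the trailing window.
#' @param history numeric vector or [ecg_record()], at least as long.
#' @return an object of class `corr_trace`: the correlation trace with the
#'   sampling rate, start time and flagged positions attached.
#' @export
cross_correlate <- function(recent, history) {
  w <- if (inherits(recent, "ecg_record")) recent$samples else as.numeric(recent)
  fs <- if (inherits(history, "ecg_record")) history$fs
        else if (inherits(recent, "ecg_record")) recent$fs else 1
  t0 <- if (inherits(history, "ecg_record")) history$t0 else 0
  h <- if (inherits(history, "ecg_record")) history$samples else as.numeric(history)
  if (length(w) < 2) stop("window must have >= 2 samples", call. = FALSE)
  if (length(h) < length(w))
    stop("history must be at least as long as the window", call. = FALSE)
  if (sd(w) < 1e-12)
    stop("degenerate input: zero-variance window", call. = FALSE)
  trace <- cpp_pearson_scan(w, h)
  flagged <- which(trace == 0)
  structure(list(trace = trace, fs = fs, t0 = t0, window = length(w),
                 flagged = flagged),
            class = "corr_trace")
}

#' @export
print.corr_trace <- function(x, ...) {
  cat(sprintf("<corr_trace> %d positions, window %d samples, max %.3f\n",
              length(x$trace), x$window, max(x$trace)))
  invisible(x)
}

#' Select phase-matched time points from a correlation trace
#'
#' Local maxima (strictly greater than both neighbours) with score at least
#' `min_score` are selected greedily in descending score, each claiming a
#' `min_separation` exclusion zone. At most `n_matches` are returned; fewer
#' (possibly none) if unavailable -- the caller decides training-mode
#' behaviour.
#'
#' @param corr a `corr_trace` from [cross_correlate()] (or a plain numeric
#'   trace, in which case `fs = 1` positions are used as times).
#' @param n_matches maximum number of matches (>= 0).
#' @param min_separation minimum spacing between matched times, seconds.
#' @param min_score minimum accepted correlation score.
#' @return an object of class `match_result` with `peak_times` (seconds,
#'   descending score order; times of the matched segment *end*),
#'   `peak_scores`, and the trace.
#' @export
find_phase_matches <- function(corr, n_matches, min_separation = 0.3,
                               min_score = 0.8) {
  if (is.numeric(corr)) corr <- structure(
    list(trace = corr, fs = 1, t0 = 0, window = 1, flagged = integer(0)),
    class = "corr_trace")
  stopifnot(inherits(corr, "corr_trace"))
  if (n_matches < 0) stop("n_matches must be >= 0", call. = FALSE)
  if (min_separation <= 0) stop("min_separation must be positive", call. = FALSE)
  tr <- corr$trace
  n <- length(tr)
  peaks <- integer(0)
  if (n >= 3) {
    core <- which(tr[2:(n - 1)] > tr[1:(n - 2)] & tr[2:(n - 1)] > tr[3:n]) + 1
    peaks <- core[tr[core] >= min_score]
  }
  peaks <- peaks[order(tr[peaks], decreasing = TRUE)]
  sep <- min_separation * corr$fs
  chosen <- integer(0)
  for (p in peaks) {
    if (length(chosen) == n_matches) break
    if (all(abs(p - chosen) >= sep)) chosen <- c(chosen, p)
  }
  # alignment position p puts the window end at sample p + window - 1
  end_times <- corr$t0 + (chosen + corr$window - 2) / corr$fs
  structure(list(peak_times = end_times, peak_scores = tr[chosen],
                 positions = chosen, corr = corr,
                 min_separation = min_separation),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> %d match(es)", length(x$peak_times)))
  if (length(x$peak_times))
    cat(sprintf(": t = %s (scores %s)",
                paste(sprintf("%.3f", x$peak_times), collapse = ", "),
                paste(sprintf("%.2f", x$peak_scores), collapse = ", ")))
  cat("\n")
  invisible(x)
}

#' Causal per-step phase-match series on the TR grid
#'
#' Computes, for every acquisition step, the phase matches that the
#' closed-loop controller would see at that step: the trailing `window_s`
#' of the TR-resampled ECG correlated against the full history up to that
#' step, excluding the most recent `n_segments` views (the current shot).
#' The result depends only on the ECG and the match configuration, so the
#' same series collates frames for closed-loop, golden-angle and random
#' logs acquired on one ECG.
#'
#' @param ecg_tr an [ecg_record()] already on the TR grid (`fs = 1/tr`).
#' @param scheme a [segmentation_scheme()].
#' @param match a [match_config()].
#' @param track carry matches forward between matchable windows: a matched
#'   phase point advances one TR per step, so steps whose trailing window is
#'   featureless (e.g. flat diastole) inherit the previous step's matches
#'   shifted by one sample instead of dropping to a partial frame.
#' @return list with `idx` (steps x (n_shots - 1) matrix of matched 1-based
#'   end steps, NA where unavailable), `raw_idx` (before tracking), `score`,
#'   and the parameters in samples.
#' @export
phase_match_series <- function(ecg_tr, scheme, match = match_config(),
                               track = TRUE) {
  stopifnot(inherits(ecg_tr, "ecg_record"), inherits(scheme, "segmentation_scheme"))
  W <- max(2L, round(match$window_s * ecg_tr$fs))
  sep <- max(1L, round(match$min_separation_s * ecg_tr$fs))
  # matches must predate the current shot (N_s views) and the refractory
  # exclusion zone around "now"
  excl <- max(scheme$n_segments, sep)
  res <- cpp_match_series(ecg_tr$samples, W, sep, match$min_score,
                          max(scheme$n_shots - 1L, 0L), excl)
  idx <- if (track) cpp_track_matches(res$idx) else res$idx
  list(idx = idx, raw_idx = res$idx, score = res$score, window = W,
       min_sep = sep, excl = excl, fs = ecg_tr$fs)
}
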