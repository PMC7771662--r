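#' Point spread function of a radial frame
#'
#' Each spoke places `n_readout` samples at `(k cos(theta), k sin(theta))`
#' with ramp density-compensation weight `max(|k|, dk/4)`; the samples are
#' gridded with a width-3 Kaiser-Bessel kernel onto a two-fold oversampled
#' Cartesian grid and inverse-FFT'd. The real part, centre-shifted, is
#' returned. `psf_average` accumulates the gridded k-space of many frames
#' before the single inverse FFT (the PSF is linear in the gridded
#' weights, so this equals the average of per-frame PSFs).
#'
#' @param angles numeric vector of view angles in degrees (one frame).
#' @param geom a [radial_geometry()].
#' @param grid_size grid size override (>= `2 * n_readout`).
#' @param frames list of angle vectors (one per frame).
#' @param deapodize divide out the gridding kernel's image-domain transform
#'   (off by default: the plain gridded estimate is returned).
#' @return a `grid_size` x `grid_size` real matrix, DC at the centre.
#' @export
psf_2d <- function(angles, geom, grid_size = geom$grid_size,
                   deapodize = FALSE) {
  psf_average(list(angles), geom, grid_size, deapodize)
}

#' @rdname psf_2d
#' @export
psf_average <- function(frames, geom, grid_size = geom$grid_size,
                        deapodize = FALSE) {
  stopifnot(inherits(geom, "radial_geometry"), length(frames) >= 1)
  G <- as.integer(grid_size)
  if (G < 2 * geom$n_readout)
    stop("grid too small: need grid_size >= 2 * n_readout", call. = FALSE)
  acc <- matrix(0, G, G)
  for (f in frames) {
    if (length(f) < 1) stop("empty frame", call. = FALSE)
    g <- cpp_grid_spokes(f, geom$n_readout, G, geom$dk,
                         kw = 3, beta = 6.486, center_frac = 0.25)
    acc <- acc + g$re
  }
  acc <- acc / length(frames)
  psf <- Re(fftshift(stats::fft(fftshift(acc), inverse = TRUE)))
  if (deapodize) {
    ap <- kb_apodization(G, kw = 3, beta = 6.486)
    psf <- psf / outer(ap, ap) * max(ap)^2
  }
  psf
}

# swap quadrants so DC moves between centre and corner
fftshift <- function(m) {
  G <- nrow(m)
  h <- G %/% 2
  m[c((h + 1):G, 1:h), c((h + 1):G, 1:h)]
}

#' Circularly symmetric PSF profile and main-lobe signal ratio
#'
#' The 2D PSF is radially averaged in 1-pixel annular bins into a profile
#' `s(r)`. The main-lobe boundary `tau` is the first sign change of `s`
#' from the centre, located sub-pixel by linear interpolation. The signal
#' ratio is the Eq-style main-lobe fraction of the symmetric 1D profile,
#' `sum_{|x| <= tau} s / sum_x s`, with the denominator either signed
#' (default) or `abs`.
#'
#' @param psf2d real PSF matrix from [psf_2d()] / [psf_average()].
#' @param geom optional [radial_geometry()] (for physical axis scaling).
#' @param denominator `"signed"` or `"abs"`.
#' @return an object of class `psf_result`: `r` (pixels), `profile`,
#'   `tau`, `mainlobe_sum`, `total_sum`, `ratio`.
#' @export
psf_profile_and_ratio <- function(psf2d, geom = NULL,
                                  denominator = c("signed", "abs")) {
  denominator <- match.arg(denominator)
  G <- nrow(psf2d)
  x <- seq_len(G) - (G %/% 2 + 1)
  rb <- round(sqrt(outer(x^2, x^2, "+")))
  prof <- tapply(psf2d, rb, mean)
  r <- as.numeric(names(prof))
  keep <- r <= G / 2 - 1
  r <- r[keep]; s <- as.numeric(prof[keep])
  cross <- which(s[-1] * s[-length(s)] < 0)
  if (length(cross) == 0)
    stop("degenerate PSF: profile has no zero crossing", call. = FALSE)
  i0 <- cross[1]
  tau <- r[i0] + s[i0] / (s[i0] - s[i0 + 1]) * (r[i0 + 1] - r[i0])
  main <- s[1] + 2 * sum(s[r > 0 & r <= tau])
  tot <- if (denominator == "signed") s[1] + 2 * sum(s[r > 0])
         else abs(s[1]) + 2 * sum(abs(s[r > 0]))
  structure(list(r = r, profile = s, tau = tau, mainlobe_sum = main,
                 total_sum = tot, ratio = main / tot,
                 denominator = denominator),
            class = "psf_result")
}

#' @export
print.psf_result <- function(x, ...) {
  cat(sprintf("<psf_result> tau = %.2f px, main-lobe ratio = %.1f%% (%s denominator)\n",
              x$tau, 100 * x$ratio, x$denominator))
  invisible(x)
}
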