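#' Dynamic ellipse phantom with analytic k-space
#'
#' A cardiac-like scene built from ellipses (body, myocardial annulus as
#' two opposite-sign ellipses, blood pool, papillary dot). The cardiac
#' ellipses contract radially with a sinusoidal cycle:
#' `scale(t) = 1 - contraction * (1 - cos(2 pi t / period)) / 2`.
#'
#' @param fov field of view, meters.
#' @param period cardiac period, seconds.
#' @param contraction peak fractional reduction of the contracting axes.
#' @param ellipses optional data frame overriding the default scene:
#'   columns `cx, cy, a, b, phi, intensity, dynamic` (centres/semi-axes in
#'   meters, rotation in radians, `dynamic` marks contracting ellipses).
#' @return an object of class `cardiac_phantom`.
#' @export
cardiac_phantom <- function(fov = 0.34, period = 1.0, contraction = 0.15,
                            ellipses = NULL) {
  if (is.null(ellipses)) {
    ellipses <- data.frame(
      cx = c(0, 0.02, 0.02, 0.02, 0.035),
      cy = c(0, 0.01, 0.01, 0.01, 0.02),
      a = c(0.140, 0.055, 0.042, 0.038, 0.006),
      b = c(0.110, 0.055, 0.042, 0.038, 0.006),
      phi = c(0, 0, 0, 0, 0),
      intensity = c(0.8, 1.0, -1.0, 0.9, 0.5),
      dynamic = c(FALSE, TRUE, TRUE, TRUE, TRUE))
  }
  if (any(ellipses$a <= 0 | ellipses$b <= 0))
    stop("semi-axes must be positive", call. = FALSE)
  if (contraction < 0 || contraction >= 1)
    stop("contraction must keep the axes positive", call. = FALSE)
  structure(list(ellipses = ellipses, fov = fov, period = period,
                 contraction = contraction),
            class = "cardiac_phantom")
}

#' @export
print.cardiac_phantom <- function(x, ...) {
  cat(sprintf("<cardiac_phantom> %d ellipses, FOV %.2f m, period %.2f s, contraction %.0f%%\n",
              nrow(x$ellipses), x$fov, x$period, 100 * x$contraction))
  invisible(x)
}

# axis scale factor of the contracting ellipses at time t
phantom_scale <- function(phantom, t) {
  1 - phantom$contraction * (1 - cos(2 * pi * t / phantom$period)) / 2
}

#' Analytic k-space of the phantom
#'
#' Exact 2D Fourier transform of the ellipse sum at cardiac phase `t`: an
#' ellipse with semi-axes a, b, rotation phi, centre c and intensity A
#' contributes `A * a * b * J1(2 pi rho) / rho * exp(-2 pi i k . c)` with
#' `rho = |(a k_u, b k_v)|` in the ellipse frame (`J1`: Bessel function of
#' the first kind; the DC limit is `A pi a b`).
#'
#' @param phantom a [cardiac_phantom()].
#' @param t time, seconds.
#' @param kx,ky k-space coordinates, 1/m (same length).
#' @return complex vector of k-space samples.
#' @export
phantom_kspace <- function(phantom, t, kx, ky) {
  stopifnot(inherits(phantom, "cardiac_phantom"), length(kx) == length(ky))
  sc <- phantom_scale(phantom, t)
  out <- complex(length(kx))
  for (j in seq_len(nrow(phantom$ellipses))) {
    e <- phantom$ellipses[j, ]
    a <- e$a * if (e$dynamic) sc else 1
    b <- e$b * if (e$dynamic) sc else 1
    ku <- kx * cos(e$phi) + ky * sin(e$phi)
    kv <- -kx * sin(e$phi) + ky * cos(e$phi)
    rho <- sqrt((a * ku)^2 + (b * kv)^2)
    amp <- numeric(length(rho))
    nz <- rho > 1e-12
    amp[nz] <- e$intensity * a * b * besselJ(2 * pi * rho[nz], 1) / rho[nz]
    amp[!nz] <- e$intensity * pi * a * b
    out <- out + amp * exp(-2i * pi * (kx * e$cx + ky * e$cy))
  }
  out
}

#' Rasterized phantom image (ground truth)
#'
#' @param phantom a [cardiac_phantom()].
#' @param t time, seconds.
#' @param n image size in pixels.
#' @param supersample supersampling factor for anti-aliased edges.
#' @return an `n` x `n` matrix covering the phantom FOV.
#' @export
phantom_image <- function(phantom, t, n = 128, supersample = 4) {
  m <- n * supersample
  # block centres land on the DFT pixel grid x = (i - n/2 - 1) * fov / n,
  # matching the convention of FFT-based reconstructions
  x <- (seq_len(m) - m / 2 - (supersample + 1) / 2) / m * phantom$fov
  sc <- phantom_scale(phantom, t)
  img <- matrix(0, m, m)
  X <- matrix(x, m, m); Y <- t(X)
  for (j in seq_len(nrow(phantom$ellipses))) {
    e <- phantom$ellipses[j, ]
    a <- e$a * if (e$dynamic) sc else 1
    b <- e$b * if (e$dynamic) sc else 1
    u <- (X - e$cx) * cos(e$phi) + (Y - e$cy) * sin(e$phi)
    v <- -(X - e$cx) * sin(e$phi) + (Y - e$cy) * cos(e$phi)
    img <- img + e$intensity * ((u / a)^2 + (v / b)^2 <= 1)
  }
  if (supersample == 1) return(img)
  # box-average supersampled pixels
  idx <- rep(seq_len(n), each = supersample)
  img <- rowsum(img, idx) / supersample
  t(rowsum(t(img), idx) / supersample)
}

#' Sample the phantom along radial spokes
#'
#' @param phantom a [cardiac_phantom()].
#' @param angles spoke angles, degrees.
#' @param times acquisition time of each spoke, seconds (recycled).
#' @param geom a [radial_geometry()].
#' @return complex matrix `length(angles)` x `n_readout`.
#' @export
acquire_spoke_samples <- function(phantom, angles, times, geom) {
  stopifnot(inherits(geom, "radial_geometry"))
  times <- rep_len(times, length(angles))
  kr <- (seq_len(geom$n_readout) - geom$n_readout / 2 - 1) * geom$dk
  out <- matrix(0i, length(angles), geom$n_readout)
  for (j in seq_along(angles)) {
    th <- angles[j] * pi / 180
    out[j, ] <- phantom_kspace(phantom, times[j], kr * cos(th), kr * sin(th))
  }
  out
}

#' Adjoint gridding reconstruction of one frame
#'
#' Ramp-weighted Kaiser-Bessel gridding of the spoke samples, inverse FFT,
#' deapodization, and central crop to the nominal FOV. Sample weights
#' approximate the radial k-space cell area `|k| dk pi / n_spokes`, so the
#' image is on the physical intensity scale of the phantom.
#'
#' @param samples complex matrix `n_spokes` x `n_readout` (zero rows give a
#'   zero image).
#' @param angles spoke angles, degrees.
#' @param geom a [radial_geometry()].
#' @return a real `n_readout` x `n_readout` image covering the FOV.
#' @export
reconstruct_frame <- function(samples, angles, geom) {
  stopifnot(inherits(geom, "radial_geometry"))
  if (length(angles) < 1) stop("empty frame", call. = FALSE)
  if (!is.matrix(samples) || nrow(samples) != length(angles) ||
      ncol(samples) != geom$n_readout)
    stop("samples must be n_spokes x n_readout", call. = FALSE)
  G <- geom$grid_size
  g <- cpp_grid_spokes(angles, geom$n_readout, G, geom$dk,
                       kw = 3, beta = 6.486, center_frac = 0.25,
                       re_ = Re(samples), im_ = Im(samples))
  kgrid <- g$re + 1i * g$im
  img <- Re(fftshift(stats::fft(fftshift(kgrid), inverse = TRUE)))
  # deapodize (divide by the kernel's image-domain transform) and scale the
  # ramp weights to radial quadrature cell areas |k| dk pi / n_spokes
  ap <- kb_apodization(G, kw = 3, beta = 6.486)
  img <- img / outer(ap, ap) * (geom$dk * pi / length(angles))
  half <- geom$n_readout / 2
  ctr <- G %/% 2 + 1
  img[(ctr - half):(ctr + half - 1), (ctr - half):(ctr + half - 1)]
}

# unnormalized image-domain transform of the width-3 Kaiser-Bessel kernel,
# sampled at the oversampled grid's pixel positions
kb_apodization <- function(G, kw = 3, beta = 6.486) {
  half <- kw / 2
  kd <- seq(-half, half, length.out = 513)
  kv <- besselI(beta * sqrt(pmax(0, 1 - (kd / half)^2)), 0)
  x <- seq_len(G) - (G %/% 2 + 1)
  vapply(x, function(xx) sum(kv * cos(2 * pi * kd * xx / G)) * (kd[2] - kd[1]),
         0)
}

#' Space-time projection map through the ventricle
#'
#' Samples each frame's intensity along a fixed line by bilinear
#' interpolation and stacks the profiles into an M-mode-like map.
#'
#' @param images list of equally sized image matrices (>= 2 frames).
#' @param line list with `x0, y0, x1, y1` in meters (origin at the image
#'   centre).
#' @param fov field of view of the images, meters.
#' @param n_points samples along the line.
#' @return matrix `n_points` x `n_frames`.
#' @export
ventricular_projection <- function(images, line, fov, n_points = 128) {
  if (length(images) < 2) stop("need at least 2 frames", call. = FALSE)
  if (max(abs(c(line$x0, line$y0, line$x1, line$y1))) > fov / 2)
    stop("line outside the field of view", call. = FALSE)
  n <- nrow(images[[1]])
  tseq <- seq(0, 1, length.out = n_points)
  # DFT pixel convention: x = 0 sits at index n/2 + 1
  px <- (line$x0 + tseq * (line$x1 - line$x0)) / fov * n + n / 2 + 1
  py <- (line$y0 + tseq * (line$y1 - line$y0)) / fov * n + n / 2 + 1
  bilinear <- function(img, x, y) {
    x <- pmin(pmax(x, 1), n - 1e-9); y <- pmin(pmax(y, 1), n - 1e-9)
    x0 <- floor(x); y0 <- floor(y)
    fx <- x - x0; fy <- y - y0
    img[cbind(x0, y0)] * (1 - fx) * (1 - fy) +
      img[cbind(x0 + 1, y0)] * fx * (1 - fy) +
      img[cbind(x0, y0 + 1)] * (1 - fx) * fy +
      img[cbind(x0 + 1, y0 + 1)] * fx * fy
  }
  vapply(images, bilinear, numeric(n_points), x = px, y = py)
}
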