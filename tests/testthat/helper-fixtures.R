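# shared fixtures and independent oracles, built in code at test time

golden_sequence <- function(n, theta0 = 0) (theta0 + (seq_len(n) - 1) * 111.25) %% 180

# brute-force uniformity oracle: explicit loops, no shared code with the
# package implementation
uniformity_oracle <- function(angles) {
  n <- length(angles)
  s <- sort(angles)
  gaps <- numeric(n - 1)
  for (j in seq_len(n - 1)) gaps[j] <- s[j + 1] - s[j]
  gaps <- sort(gaps)
  num <- 0
  cs <- 0
  for (k in seq_len(n - 1)) {
    cs <- cs + gaps[k]
    num <- num + cs
  }
  den <- 0
  for (k in seq_len(n - 1)) den <- den + k * (180 / n)
  num / den
}

# brute-force Pearson correlation scan oracle
pearson_scan_oracle <- function(window, history) {
  W <- length(window)
  out <- numeric(length(history) - W + 1)
  for (p in seq_along(out)) {
    seg <- history[p:(p + W - 1)]
    if (sd(seg) < 1e-12 || sd(window) < 1e-12) { out[p] <- 0; next }
    out[p] <- suppressWarnings(cor(window, seg))
  }
  out
}

# direct-DFT PSF oracle: sum of ramp-weighted plane waves on the image grid
psf_dft_oracle <- function(angles, geom, grid_size) {
  Nr <- geom$n_readout
  kr <- ((-Nr / 2):(Nr / 2 - 1)) * geom$dk
  w <- pmax(abs(kr), geom$dk / 4)
  dkg <- Nr * geom$dk / grid_size
  xs <- ((seq_len(grid_size) - (grid_size %/% 2 + 1))) / (grid_size * dkg)
  psf <- matrix(0, grid_size, grid_size)
  for (th_deg in angles) {
    th <- th_deg * pi / 180
    kx <- kr * cos(th); ky <- kr * sin(th)
    ex <- exp(2i * pi * outer(xs, kx))           # grid_size x Nr
    ey <- exp(2i * pi * outer(xs, ky))
    psf <- psf + Re(ex %*% (w * t(ey)))           # sum_j w_j ex[,j] ey[,j]^T
  }
  psf
}

sinus_ecg <- function(duration = 40, rr_sd = 0.05, seed = 7, noise_sd = 0.02) {
  generate_ecg(rhythm_spec(rr_mean = 1.0, rr_sd = rr_sd, noise_sd = noise_sd,
                           seed = seed), duration, fs = 400)
}

# rasterized truth band-limited to the acquired k-space disc (the recon
# cannot contain energy beyond k_max, so this is the attainable reference)
bandlimited_truth <- function(phantom, t, geom) {
  n <- geom$n_readout
  img <- phantom_image(phantom, t, n = n, supersample = 4)
  sh <- function(m) { h <- n %/% 2; m[c((h + 1):n, 1:h), c((h + 1):n, 1:h)] }
  K <- sh(stats::fft(sh(img)))
  x <- seq_len(n) - (n %/% 2 + 1)
  keep <- sqrt(outer(x^2, x^2, "+")) <= n / 2
  Re(sh(stats::fft(sh(K * keep), inverse = TRUE))) / n^2
}
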