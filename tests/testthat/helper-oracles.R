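# Shared oracles and small fixtures, all built in code.

# Brute-force pupil-rescaling oracle: sample the original wavefront on a
# dense grid restricted to the smaller concentric pupil and least-squares
# refit Zernike coefficients there. Independent of the analytic transform.
refit_rescaled <- function(z, new_radius, n_side = 61) {
  eps <- new_radius / z$pupil_radius
  ax <- seq(-1, 1, length.out = n_side)
  pts <- expand.grid(x = ax, y = ax)
  pts <- pts[pts$x^2 + pts$y^2 <= 1, ]
  rho_new <- sqrt(pts$x^2 + pts$y^2)
  theta <- atan2(pts$y, pts$x)
  jmax <- length(z$coeffs) - 1L
  # original wavefront at these physical points (rho_old = eps * rho_new)
  W <- rep(0, nrow(pts))
  for (j in 0:jmax) {
    cj <- z$coeffs[j + 1L]
    if (cj != 0) W <- W + cj * zernike_poly(j, eps * rho_new, theta)
  }
  X <- vapply(0:jmax, function(j) zernike_poly(j, rho_new, theta),
              numeric(nrow(pts)))
  fit <- stats::lm.fit(X, W)
  zernike_coefficients(stats::setNames(fit$coefficients, 0:jmax), new_radius)
}

# Direct discrete-Fourier-transform PSF on a small pupil: explicit complex
# exponential kernel, no FFT, centred on pixel n/2 + 1.
direct_dft_psf <- function(pf) {
  g <- pf$grid
  n <- g$n_fft
  big <- matrix(0 + 0i, n, n)
  off <- (n - g$n_pupil) %/% 2
  idx <- off + seq_len(g$n_pupil)
  big[idx, idx] <- pf$P
  c0 <- n %/% 2 + 1
  k <- seq_len(n) - c0
  E <- exp(-2i * pi * outer(k, k) / n)
  F <- E %*% big %*% E
  psf <- Re(F * Conj(F))
  psf / sum(psf)
}

# Count intensity minima along a radial profile (fringe counting).
count_fringe_minima <- function(profile) {
  d <- diff(profile)
  sum(d[-length(d)] < 0 & d[-1] > 0)
}

# Axis difference folded to [0, 90] degrees.
axis_diff <- function(a, b) {
  d <- abs(a %% 180 - b %% 180)
  min(d, 180 - d)
}

# 180-degree rotation of an image about the centre pixel (odd-extent core).
rot180_core <- function(m) {
  m2 <- m[2:nrow(m), 2:ncol(m), drop = FALSE]
  m2[rev(seq_len(nrow(m2))), rev(seq_len(ncol(m2))), drop = FALSE]
}

ink_extent_arcmin <- function(chart) {
  ink <- chart$background - chart$image > 0.5
  rows <- range(which(apply(ink, 1, any)))
  cols <- range(which(apply(ink, 2, any)))
  c(height = (rows[2] - rows[1] + 1) * chart$pixel_scale,
    width = (cols[2] - cols[1] + 1) * chart$pixel_scale)
}
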