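test_that("zero-phase PSF is an Airy pattern with the textbook first minimum", {
  g <- grid_spec(2)                       # 4-mm pupil, 587 nm
  psf <- compute_psf(pupil_function(zero_wavefront(g)))
  n <- g$n_fft; c0 <- n %/% 2 + 1
  # peak on the centre pixel, unit sum
  expect_equal(which(psf$intensity == max(psf$intensity)),
               (c0 - 1) * n + c0)
  expect_equal(sum(psf$intensity), 1, tolerance = 1e-12)
  # first radial minimum at 1.22 lambda / D = 0.6155 arcmin, within one pixel
  prof <- psf$intensity[c0, c0:(c0 + 30)]
  first_min <- (which(diff(prof) > 0)[1] - 1) * psf$pixel_scale
  expect_lt(abs(first_min - 1.22 * 587e-9 / 4e-3 * 180 / pi * 60),
            psf$pixel_scale + 1e-12)
})

test_that("small-aberration Strehl follows the Marechal approximation", {
  g <- grid_spec(2)
  for (sigma in 587e-3 / c(14, 20, 30)) {   # RMS in um, up to lambda/14
    z <- zernike_coefficients(c("4" = sigma), 2)
    s <- strehl_ratio(evaluate_wavefront(z, g))
    expect_equal(s, exp(-(2 * pi * sigma / 0.587)^2), tolerance = 0.02)
  }
})

test_that("FFT-based PSF equals a direct Fourier summation on a small pupil", {
  g <- grid_spec(1.5, n_pupil = 32, pad_factor = 2)
  z <- zernike_coefficients(c("4" = 0.3), 1.5)
  pf <- pupil_function(evaluate_wavefront(z, g))
  a <- compute_psf(pf)$intensity
  b <- direct_dft_psf(pf)
  expect_lt(max(abs(a - b)) / max(b), 1e-10)
})

test_that("PSF is piston-invariant and translated by tilt without reshaping", {
  g <- grid_spec(2, n_pupil = 64)
  base <- compute_psf(pupil_function(zero_wavefront(g)))$intensity
  withp <- compute_psf(pupil_function(
    evaluate_wavefront(zernike_coefficients(c("0" = 1.7), 2), g)))$intensity
  expect_lt(max(abs(base - withp)), 1e-12)

  # vertical tilt chosen to shift the PSF by an integer pixel count
  shift_px <- 5
  dtheta <- g$pixel_scale / 60 * pi / 180
  c_tilt <- shift_px * dtheta * g$pupil_radius * 1e3 / 2   # um
  wt <- compute_psf(pupil_function(
    evaluate_wavefront(zernike_coefficients(c("1" = c_tilt), 2), g)))$intensity
  n <- nrow(base); c0 <- n %/% 2 + 1
  peak <- which(wt == max(wt), arr.ind = TRUE)
  expect_equal(unname(peak[1, "col"]), c0)
  expect_equal(abs(unname(peak[1, "row"]) - c0), shift_px)
  # shape preserved: translated copy matches the unaberrated PSF
  rows <- (1 + shift_px):(n - shift_px)
  moved <- if (peak[1, "row"] > c0) wt[rows + shift_px, ] else wt[rows - shift_px, ]
  expect_lt(max(abs(moved - base[rows, ])), 1e-6)
})

test_that("doubling the padding changes Strehl and Visual Strehl by < 1%", {
  z <- make_eye("P2_like", seed = 2)
  for (pads in list(c(4, 8))) {
    g1 <- grid_spec(2, n_pupil = 128, pad_factor = pads[1])
    g2 <- grid_spec(2, n_pupil = 128, pad_factor = pads[2])
    e <- schematic_eye(z, 2)
    vs1 <- visual_strehl(total_phase(e, grid = g1))
    vs2 <- visual_strehl(total_phase(e, grid = g2))
    expect_lt(abs(vs1 - vs2) / vs2, 0.01)
    s1 <- strehl_ratio(total_phase(e, grid = g1))
    s2 <- strehl_ratio(total_phase(e, grid = g2))
    expect_lt(abs(s1 - s2) / s2, 0.01)
  }
})

test_that("anamorphic magnification scales geometry as prescribed", {
  # identity magnification returns the chart untouched
  ch <- make_dot_pattern()
  expect_identical(apply_magnification(ch, c(1, 1, 0))$image, ch$image)

  # isotropic x2 on a disc: area ratio 4
  n <- 201
  ax <- seq(-50, 50, length.out = n)
  disc <- 1 - outer(ax, ax, function(y, x) as.numeric(x^2 + y^2 <= 15^2))
  chd <- chart(disc, pixel_scale = 0.5)
  mag <- apply_magnification(chd, c(2, 2, 0))
  area0 <- sum(1 - chd$image); area1 <- sum(1 - mag$image)
  expect_equal(area1 / area0, 4, tolerance = 0.02)

  # anamorphic 1.08 x 1.00 at meridian 0: width stretches, height does not
  sq <- matrix(1, n, n)
  sq[76:126, 76:126] <- 0
  chs <- chart(sq, pixel_scale = 0.5)
  ms <- apply_magnification(chs, c(1.08, 1.00, 0))
  ext <- ink_extent_arcmin(ms)
  expect_equal(ext[["width"]] / ext[["height"]], 1.08, tolerance = 0.03)
  expect_equal(ext[["height"]], 51 * 0.5, tolerance = 0.5)
  expect_error(apply_magnification(chs, c(-1, 1, 0)), "positive")
})

test_that("retinal-image convolution is flux-conserving and delta-correct", {
  g <- grid_spec(3, n_pupil = 64)
  psf <- compute_psf(pupil_function(
    evaluate_wavefront(zernike_coefficients(c("4" = 0.4), 3), g)))
  # delta-function chart reproduces the PSF kernel
  k <- refractsim:::crop_psf_kernel(psf)
  hk <- (nrow(k) - 1) %/% 2
  nch <- nrow(k) + 40; cc <- (nch + 1) %/% 2
  m <- matrix(1, nch, nch); m[cc, cc] <- 0
  delta <- chart(m, pixel_scale = psf$pixel_scale)
  out <- render_retinal_image(delta, psf)
  got <- 1 - out$image[cc + (-hk:hk), cc + (-hk:hk)]
  expect_lt(max(abs(got - k)), 1e-9)
  # mean intensity conserved (margin wide enough that no blur leaves the
  # canvas: the unit-sum kernel then redistributes flux without loss)
  ch <- make_letter_line(0.4, "HNZ", pixel_scale = psf$pixel_scale,
                         margin = 12)
  img <- render_retinal_image(ch, psf)
  expect_equal(mean(img$image), mean(ch$image), tolerance = 1e-6)
  # diffraction-limited large letters: near-identity convolution
  psf0 <- compute_psf(pupil_function(zero_wavefront(g)))
  big <- make_letter_line(1.0, "HN", pixel_scale = psf0$pixel_scale)
  out0 <- render_retinal_image(big, psf0)
  expect_gt(stats::cor(as.vector(out0$image), as.vector(big$image)), 0.99)
})

test_that("interferograms count fringes and keep crossed-cylinder symmetry", {
  g <- grid_spec(2, n_pupil = 256)
  # zero phase: uniformly bright disc
  ifg0 <- render_interferogram(zero_wavefront(g))
  W0 <- zero_wavefront(g)
  expect_true(all(ifg0[W0$mask] == 1))
  expect_true(all(ifg0[!W0$mask] == 0))
  # pure defocus: ring count = peak-to-valley / lambda (+-1)
  z <- zernike_coefficients(c("4" = 1), 2)
  W <- evaluate_wavefront(z, g)
  ifg <- render_interferogram(W)
  c0 <- g$n_pupil %/% 2 + 1
  prof <- ifg[c0, c0:(c0 + g$n_pupil %/% 2 - 2)]
  pv <- 2 * sqrt(3) * 1
  expect_lt(abs(count_fringe_minima(prof) - pv / 0.587), 1.5)
  # JCC phase: saddle fringes symmetric under 180-degree rotation
  Wj <- jcc_phase(jcc_state(0.5, axis = 30), 0, g)
  ifj <- render_interferogram(Wj)
  expect_lt(max(abs(rot180_core(ifj) -
                    ifj[2:nrow(ifj), 2:ncol(ifj)])), 1e-9)
})
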