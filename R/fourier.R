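# Fourier-optics image formation: complex pupil function, PSF as the squared
# modulus of its Fourier transform, OTF, anamorphic paraxial image, and
# convolution to the retinal image. All imagery lives in visual-angle
# coordinates (arcmin); conversion to retinal microns via the eye's focal
# length is a reporting utility only.

#' Complex pupil function
#'
#' `P(x, y) = p(x, y) exp(-i 2 pi W_T(x, y) / lambda)` with a circular
#' top-hat amplitude `p`.
#'
#' @param wavefront a `wavefront_map` (micrometres) from
#'   [evaluate_wavefront()], [total_phase()] etc.
#' @param grid a [grid_spec()]; defaults to the wavefront's grid.
#' @return An object of class `pupil_function`: complex matrix `P`,
#'   logical `amplitude` mask and the `grid`.
#' @export
pupil_function <- function(wavefront, grid = wavefront$grid) {
  stopifnot(inherits(wavefront, "wavefront_map"))
  if (any(!is.finite(wavefront$values[wavefront$mask])))
    stop("wavefront contains non-finite values inside the pupil")
  lambda_um <- grid$wavelength * 1e-3
  P <- ifelse(wavefront$mask, 1, 0) *
    exp(-2i * pi * wavefront$values / lambda_um)
  P[!wavefront$mask] <- 0
  structure(list(P = P, amplitude = wavefront$mask, grid = grid),
            class = "pupil_function")
}

# Checkerboard (-1)^(i+j) used to centre the FFT on pixel n/2 + 1.
checkerboard <- function(n) {
  s <- (-1)^(seq_len(n) - 1)
  outer(s, s)
}

#' Point-spread function of a pupil function
#'
#' `PSF = |FFT(P)|^2`, computed on the zero-padded `n_fft` grid, centred on
#' pixel `n_fft/2 + 1`, and normalized to unit sum. The angular pixel scale
#' comes from the [grid_spec()].
#'
#' @param pf a [pupil_function()].
#' @return An object of class `psf_image`: `intensity` matrix (unit sum),
#'   `pixel_scale` (arcmin/px) and the `grid`.
#' @export
compute_psf <- function(pf) {
  stopifnot(inherits(pf, "pupil_function"))
  g <- pf$grid
  n <- g$n_fft
  big <- matrix(0 + 0i, n, n)
  off <- (n - g$n_pupil) %/% 2
  idx <- off + seq_len(g$n_pupil)
  big[idx, idx] <- pf$P
  # pre-multiplying by (-1)^(i+j) shifts the spectrum so DC lands on the
  # centre pixel; the squared modulus needs no post-shift
  big <- big * checkerboard(n)
  F <- stats::fft(big)
  psf <- Re(F * Conj(F))
  psf <- psf / sum(psf)
  structure(list(intensity = psf, pixel_scale = g$pixel_scale, grid = g),
            class = "psf_image")
}

#' Strehl ratio of a wavefront
#'
#' Peak of the aberrated PSF divided by the peak of the diffraction-limited
#' PSF on the same pupil and grid.
#' @param wavefront a `wavefront_map`.
#' @param grid a [grid_spec()] (defaults to the wavefront's).
#' @return scalar Strehl ratio.
#' @export
strehl_ratio <- function(wavefront, grid = wavefront$grid) {
  psf <- compute_psf(pupil_function(wavefront, grid))
  psf0 <- compute_psf(pupil_function(zero_wavefront(grid), grid))
  max(psf$intensity) / max(psf0$intensity)
}

#' Interferogram of a wavefront
#'
#' Two-beam interference rendering of the phase:
#' `I = (1 + cos(2 pi W / lambda)) / 2` inside the pupil, 0 outside. One
#' fringe period corresponds to one wavelength of optical path difference.
#'
#' @param wavefront a `wavefront_map` (micrometres).
#' @param wavelength wavelength in nm (defaults to the grid's).
#' @return numeric matrix in `[0, 1]`.
#' @export
render_interferogram <- function(wavefront,
                                 wavelength = wavefront$grid$wavelength) {
  stopifnot(inherits(wavefront, "wavefront_map"))
  lambda_um <- wavelength * 1e-3
  img <- 0.5 * (1 + cos(2 * pi * wavefront$values / lambda_um))
  img[!wavefront$mask] <- 0
  img
}

# Bilinear sampler: values of `img` at (row, col) positions (matrices or
# vectors), constant `fill` outside. Rows/cols are 1-based fractional indices.
bilinear_sample <- function(img, rows, cols, fill = 0) {
  nr <- nrow(img); nc <- ncol(img)
  r0 <- floor(rows); c0 <- floor(cols)
  fr <- rows - r0; fc <- cols - c0
  get <- function(r, c) {
    ok <- r >= 1 & r <= nr & c >= 1 & c <= nc
    v <- rep(fill, length(r))
    v[ok] <- img[cbind(r[ok], c[ok])]
    v
  }
  v00 <- get(r0, c0); v01 <- get(r0, c0 + 1)
  v10 <- get(r0 + 1, c0); v11 <- get(r0 + 1, c0 + 1)
  out <- v00 * (1 - fr) * (1 - fc) + v01 * (1 - fr) * fc +
    v10 * fr * (1 - fc) + v11 * fr * fc
  matrix(out, nrow = nrow(rows), ncol = ncol(rows))
}

#' Apply anamorphic spectacle magnification to a chart
#'
#' Scales the paraxial image by `sm_axis` along the stated meridian and
#' `sm_perp` perpendicular to it (rotate-scale-rotate about the image
#' centre), with bilinear resampling on the preserved canvas. Newly exposed
#' canvas is filled with the chart background.
#'
#' @param chart a [chart()] object.
#' @param sm either a scalar magnification, a length-2/3 numeric vector
#'   `(sm1, sm2[, meridian_deg])`, or the list returned by
#'   [spectacle_magnification()] for a sphero-cylinder.
#' @return the magnified `chart` (same canvas and pixel scale).
#' @export
apply_magnification <- function(chart, sm) {
  stopifnot(inherits(chart, "chart"))
  if (is.list(sm)) sm <- c(sm$sm_axis, sm$sm_perp, sm$meridian_deg)
  if (length(sm) == 1) sm <- c(sm, sm, 0)
  if (length(sm) == 2) sm <- c(sm, 0)
  if (any(sm[1:2] <= 0)) stop("magnification components must be positive")
  if (all(abs(sm[1:2] - 1) < 1e-12)) return(chart)
  img <- chart$image
  nr <- nrow(img); nc <- ncol(img)
  cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
  a <- sm[3] * pi / 180
  R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)       # rotate by +a
  Minv <- R %*% diag(1 / sm[1:2]) %*% t(R)                    # inverse map
  co <- matrix(rep(seq_len(nc) - cx, each = nr), nr, nc)      # x offsets
  ro <- matrix(rep(seq_len(nr) - cy, times = nc), nr, nc)     # y offsets
  # image rows run down the y axis; work in (x, y) with y = -row offset
  xs <- Minv[1, 1] * co + Minv[1, 2] * (-ro)
  ys <- Minv[2, 1] * co + Minv[2, 2] * (-ro)
  chart$image <- bilinear_sample(img, cy - ys, cx + xs, fill = chart$background)
  chart
}

# Resample a chart to a new pixel scale (pure isotropic rescale about centre).
resample_chart <- function(chart, new_pixel_scale) {
  ratio <- chart$pixel_scale / new_pixel_scale
  if (abs(ratio - 1) < 1e-9) return(chart)
  nr <- max(3L, as.integer(round(nrow(chart$image) * ratio)))
  nc <- max(3L, as.integer(round(ncol(chart$image) * ratio)))
  cy <- (nrow(chart$image) + 1) / 2; cx <- (ncol(chart$image) + 1) / 2
  ny <- (nr + 1) / 2; nx <- (nc + 1) / 2
  rows <- matrix(rep((seq_len(nr) - ny) / ratio + cy, times = nc), nr, nc)
  cols <- matrix(rep((seq_len(nc) - nx) / ratio + cx, each = nr), nr, nc)
  chart$image <- bilinear_sample(chart$image, rows, cols,
                                 fill = chart$background)
  chart$pixel_scale <- new_pixel_scale
  chart
}

# Crop a PSF to the smallest centred odd-size kernel holding all but
# `loss` of its energy, renormalized to unit sum.
crop_psf_kernel <- function(psf, loss = 1e-8) {
  I <- psf$intensity
  n <- nrow(I)
  c0 <- n %/% 2 + 1
  # cumulative energy in centred square windows
  half_max <- min(c0 - 1L, n - c0)   # keep the kernel odd and centred
  half <- 1L
  repeat {
    idx <- (c0 - half):(c0 + half)
    e <- sum(I[idx, idx])
    if (e >= 1 - loss || half >= half_max) break
    half <- min(half + max(1L, half %/% 2L), half_max)
  }
  k <- I[idx, idx]
  k / sum(k)
}

# Linear FFT convolution of two matrices, returning the "same" extent as `a`.
fft_convolve_same <- function(a, k) {
  nr <- nrow(a) + nrow(k) - 1L
  nc <- ncol(a) + ncol(k) - 1L
  # next size with small prime factors for FFT speed
  good_size <- function(n) {
    while (TRUE) {
      m <- n
      for (p in c(2, 3, 5, 7)) while (m %% p == 0) m <- m / p
      if (m == 1) return(n)
      n <- n + 1
    }
  }
  NR <- good_size(nr); NC <- good_size(nc)
  A <- matrix(0, NR, NC); A[seq_len(nrow(a)), seq_len(ncol(a))] <- a
  K <- matrix(0, NR, NC); K[seq_len(nrow(k)), seq_len(ncol(k))] <- k
  full <- Re(stats::fft(stats::fft(A) * stats::fft(K), inverse = TRUE)) / (NR * NC)
  r0 <- (nrow(k) + 1) %/% 2; c0 <- (ncol(k) + 1) %/% 2
  full[r0 + seq_len(nrow(a)) - 1, c0 + seq_len(ncol(a)) - 1]
}

#' Convolve a chart with a PSF to form the retinal image
#'
#' The chart is resampled to the PSF pixel scale, converted to an emission
#' image (ink bright on dark), convolved with the unit-sum PSF kernel in the
#' frequency domain, and converted back to the chart's luminance convention.
#' Mean intensity is conserved.
#'
#' @param chart a [chart()] object.
#' @param psf a `psf_image` from [compute_psf()].
#' @param max_fft guard on the convolution grid size (default 4096); larger
#'   fields abort rather than alias.
#' @return An object of class `retinal_image`: `image` (luminance matrix),
#'   `pixel_scale` (arcmin/px), `chart_kind`.
#' @export
render_retinal_image <- function(chart, psf, max_fft = 4096) {
  stopifnot(inherits(chart, "chart"), inherits(psf, "psf_image"))
  chart <- resample_chart(chart, psf$pixel_scale)
  k <- crop_psf_kernel(psf)
  if (nrow(chart$image) + nrow(k) - 1 > max_fft ||
      ncol(chart$image) + ncol(k) - 1 > max_fft)
    stop("chart plus PSF support exceeds the maximum convolution field (",
         max_fft, " px); reduce the chart size or coarsen the sampling")
  emission <- chart$background - chart$image
  blurred <- fft_convolve_same(emission, k)
  img <- chart$background - blurred
  structure(list(image = img, pixel_scale = psf$pixel_scale,
                 chart_kind = chart$kind, background = chart$background,
                 dial = chart$dial),
            class = "retinal_image")
}

#' Convert visual angle to retinal distance
#'
#' Reporting utility: arcmin of visual angle to micrometres on the retina of
#' a reduced eye, `x = f * tan(theta) / n'` with the image-space index.
#' @param arcmin angle in arcmin.
#' @param focal_length eye focal length in mm (default 22.4).
#' @return retinal extent in micrometres.
#' @export
arcmin_to_retinal_um <- function(arcmin, focal_length = 22.4) {
  focal_length * 1e3 * tan(arcmin / 60 * pi / 180)
}

#' Write a grayscale image, chart, PSF or retinal image to PNG
#'
#' Images are clamped to `[0, 1]`; PSFs are peak-normalized (optionally
#' gamma-compressed) before writing.
#' @param x a matrix in `[0, 1]`, `chart`, `psf_image` or `retinal_image`.
#' @param path output file path.
#' @param gamma exponent applied for display (default 1; use ~0.5 for PSFs).
#' @return `path`, invisibly.
#' @export
write_image_png <- function(x, path, gamma = 1) {
  img <- if (inherits(x, "psf_image")) x$intensity / max(x$intensity)
  else if (inherits(x, c("chart", "retinal_image"))) x$image
  else x
  img <- pmin(pmax(img, 0), 1)^gamma
  png::writePNG(img, target = path)
  invisible(path)
}
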