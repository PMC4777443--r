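# Sampling geometry shared by wavefront maps, pupil functions and PSFs.

#' Pupil/PSF sampling specification
#'
#' Defines the discrete geometry of the simulation: `n_pupil` samples across
#' the pupil diameter, zero-padded by `pad_factor` for the FFT, monochromatic
#' wavelength. The PSF angular sampling that follows is
#' `dtheta = lambda / (n_fft * dx)` radians with `dx = 2 * pupil_radius /
#' n_pupil`, reported in arcmin per pixel.
#'
#' @param pupil_radius pupil radius in mm (> 0).
#' @param n_pupil samples across the pupil diameter (default 256).
#' @param pad_factor integer zero-padding factor >= 2 (default 4).
#' @param wavelength wavelength in nm (default 587).
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(pupil_radius, n_pupil = 256, pad_factor = 4,
                      wavelength = 587) {
  stopifnot(pupil_radius > 0, n_pupil >= 8, pad_factor >= 2, wavelength > 0)
  n_pupil <- as.integer(n_pupil)
  pad_factor <- as.integer(pad_factor)
  n_fft <- n_pupil * pad_factor
  dx_mm <- 2 * pupil_radius / n_pupil
  dtheta_rad <- (wavelength * 1e-9) / (n_fft * dx_mm * 1e-3)
  structure(list(
    pupil_radius = pupil_radius, n_pupil = n_pupil, pad_factor = pad_factor,
    wavelength = wavelength, n_fft = n_fft, dx_mm = dx_mm,
    pixel_scale = dtheta_rad * 180 / pi * 60   # arcmin per PSF pixel
  ), class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf(
    "<grid_spec> pupil radius %.3g mm, %d px across diameter, pad x%d,\n",
    x$pupil_radius, x$n_pupil, x$pad_factor))
  cat(sprintf("  lambda %g nm, PSF sampling %.4g arcmin/px, field %.4g arcmin\n",
              x$wavelength, x$pixel_scale, x$pixel_scale * x$n_fft))
  invisible(x)
}

# Physical pupil-plane coordinates (mm) of the n_pupil x n_pupil samples.
# Index n_pupil/2 + 1 sits at the origin (even-size FFT convention).
grid_coords <- function(grid) {
  n <- grid$n_pupil
  x <- (seq_len(n) - 1 - n %/% 2) * grid$dx_mm
  list(x = x, y = x)
}
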