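# Objective image/optical quality metrics: Visual Strehl (VSOTF variant),
# clock-dial line sharpness, image-pair similarity, through-focus curves and
# a template-correlation visual-acuity estimator.

# Session-independent caches (diffraction-limited PSFs, acuity templates).
.metric_cache <- new.env(parent = emptyenv())

grid_signature <- function(grid) {
  paste(grid$n_pupil, grid$pad_factor, signif(grid$pupil_radius, 10),
        signif(grid$wavelength, 10), sep = "|")
}

cached <- function(key, expr) {
  if (!is.null(.metric_cache[[key]])) return(.metric_cache[[key]])
  val <- force(expr)
  assign(key, val, envir = .metric_cache)
  val
}

diffraction_limited_psf <- function(grid) {
  cached(paste0("dlpsf|", grid_signature(grid)),
         compute_psf(pupil_function(zero_wavefront(grid), grid)))
}

#' Neural contrast-sensitivity weight
#'
#' Radially symmetric band-pass weight used inside the Visual Strehl ratio:
#' `CSF_N(f) = (f / f_peak) * exp(1 - f / f_peak)` with `f_peak = 4` cycles
#' per degree, truncated at 60 cpd. Only the shape matters: the Visual Strehl
#' ratio is invariant to the overall CSF scale.
#'
#' @param f spatial frequency in cycles per degree (vectorized).
#' @param peak peak frequency in cpd (default 4).
#' @param cutoff truncation frequency in cpd (default 60).
#' @return weight values in `[0, 1]`.
#' @export
neural_csf <- function(f, peak = 4, cutoff = 60) {
  w <- (f / peak) * exp(1 - f / peak)
  w[f <= 0 | f > cutoff] <- 0
  w
}

# OTF (complex, DC at element [1,1] equal to 1) of a centred unit-sum PSF.
psf_to_otf <- function(psf_matrix) {
  n <- nrow(psf_matrix)
  c0 <- n %/% 2 + 1
  shift <- c(c0:n, seq_len(c0 - 1))   # move centre pixel to [1,1]
  stats::fft(psf_matrix[shift, shift])
}

# |f| grid (cycles/degree) in native FFT ordering for a PSF sampled at
# pixel_scale arcmin/px.
otf_freq_cpd <- function(n, pixel_scale_arcmin) {
  df <- 1 / (n * pixel_scale_arcmin / 60)   # cycles per degree
  k <- c(0:(n %/% 2 - 1), -(n - n %/% 2):-1)
  f <- k * df
  sqrt(outer(f^2, f^2, "+"))
}

#' Visual Strehl ratio (VSOTF)
#'
#' CSF-weighted volume of the real part of the aberrated OTF relative to the
#' diffraction-limited OTF on the same pupil:
#' `VS = sum(CSF_N * Re(OTF)) / sum(CSF_N * Re(OTF_DL))`. Equals 1 for a
#' zero-phase pupil by construction.
#'
#' @param wavefront a `wavefront_map` (micrometres).
#' @param grid a [grid_spec()] (defaults to the wavefront's grid).
#' @return scalar Visual Strehl ratio.
#' @export
visual_strehl <- function(wavefront, grid = wavefront$grid) {
  psf <- compute_psf(pupil_function(wavefront, grid))
  visual_strehl_psf(psf)
}

# VS from an already-computed PSF (shared by procedures to avoid recomputes).
visual_strehl_psf <- function(psf) {
  g <- psf$grid
  key <- paste0("vsdenom|", grid_signature(g))
  wts <- cached(paste0("csfw|", grid_signature(g)),
                neural_csf(otf_freq_cpd(g$n_fft, psf$pixel_scale)))
  denom <- cached(key, {
    otf_dl <- psf_to_otf(diffraction_limited_psf(g)$intensity)
    sum(wts * Re(otf_dl))
  })
  otf <- psf_to_otf(psf$intensity)
  sum(wts * Re(otf)) / denom
}

#' Per-line sharpness scores of a rendered clock-dial image
#'
#' Automated surrogate for "which line looks sharpest": for each of the 12
#' dial radii the score is the mean gradient magnitude transverse to the line
#' direction within an annular region of interest around that radius. Sharper
#' lines preserve their transverse edge gradients; lines blurred across their
#' length lose them.
#'
#' @param img a `retinal_image` rendered from a [make_clock_dial()] chart.
#' @return A list: `scores` (named numeric, orientations 0, 30, ..., 330
#'   degrees), `sharpest_deg` (argmax orientation), `cv` (coefficient of
#'   variation of the scores), `spread` (max/min - 1).
#' @export
dial_line_sharpness <- function(img) {
  stopifnot(inherits(img, "retinal_image"))
  if (!identical(img$chart_kind, "clock_dial"))
    stop("dial_line_sharpness needs an image rendered from a clock-dial chart")
  geom <- img$dial
  if (is.null(geom)) stop("retinal image carries no dial geometry")
  I <- img$background - img$image          # work on the emission image
  nr <- nrow(I); nc <- ncol(I)
  gx <- matrix(0, nr, nc); grow <- matrix(0, nr, nc)
  gx[, 2:(nc - 1)] <- (I[, 3:nc] - I[, 1:(nc - 2)]) / 2
  grow[2:(nr - 1), ] <- (I[3:nr, ] - I[1:(nr - 2), ]) / 2
  gy <- -grow                              # rows run down the y axis
  ps <- img$pixel_scale
  ax_x <- (seq_len(nc) - (nc + 1) / 2) * ps
  ax_y <- rev((seq_len(nr) - (nr + 1) / 2) * ps)
  X <- matrix(rep(ax_x, each = nr), nr, nc)
  Y <- matrix(rep(ax_y, times = nc), nr, nc)
  r_lo <- max(geom$r_in + geom$line_width, 0.35 * geom$r_out)
  r_hi <- 0.95 * geom$r_out
  halfw <- 1.5 * geom$line_width
  phis <- (0:11) * 30
  scores <- vapply(phis, function(phi_deg) {
    phi <- phi_deg * pi / 180
    s <- X * cos(phi) + Y * sin(phi)
    d <- -X * sin(phi) + Y * cos(phi)
    roi <- s >= r_lo & s <= r_hi & abs(d) <= halfw
    gt <- -gx[roi] * sin(phi) + gy[roi] * cos(phi)
    mean(abs(gt))
  }, numeric(1))
  names(scores) <- phis
  m <- mean(scores)
  list(scores = scores,
       sharpest_deg = phis[which.max(scores)],
       cv = if (m > 0) stats::sd(scores) / m else 0,
       spread = if (min(scores) > 0) max(scores) / min(scores) - 1 else Inf)
}

#' Similarity between two retinal images
#'
#' Symmetric score in `[0, 1]`: the Pearson cross-correlation of the two
#' pixel arrays (negative correlations clamp to 0). Identical images score 1.
#'
#' @param a,b `retinal_image` objects with the same pixel scale and extent.
#' @return scalar similarity.
#' @export
image_pair_similarity <- function(a, b) {
  stopifnot(inherits(a, "retinal_image"), inherits(b, "retinal_image"))
  if (!all(dim(a$image) == dim(b$image)))
    stop("images differ in extent")
  if (abs(a$pixel_scale - b$pixel_scale) > 1e-9)
    stop("images differ in pixel scale")
  va <- as.vector(a$image); vb <- as.vector(b$image)
  if (stats::sd(va) == 0 || stats::sd(vb) == 0)
    return(as.numeric(isTRUE(all.equal(va, vb))))
  max(0, stats::cor(va, vb))
}

# Template-match score used by the acuity estimator: the regression slope of
# the rendered image on the template (both mean-subtracted). Unlike a plain
# correlation it retains the image contrast — a washed-out image scores near
# zero against every template instead of matching sub-visible residuals.
template_match <- function(img, tmpl) {
  a <- as.vector(img) - mean(img)
  b <- as.vector(tmpl) - mean(tmpl)
  nb <- sum(b * b)
  if (nb == 0) return(0)
  sum(a * b) / nb
}

acuity_template <- function(grid, logmar, orientation) {
  key <- paste0("tmpl|", grid_signature(grid), "|", logmar, "|", orientation)
  cached(key, {
    ch <- make_snellen_e(logmar, orientation, pixel_scale = grid$pixel_scale)
    render_retinal_image(ch, diffraction_limited_psf(grid))
  })
}

#' Template-correlation visual-acuity estimate
#'
#' Surrogate for a letter-chart acuity measurement: the smallest logMAR size
#' (0.1-step grid, -0.3 to 1.3) at which the scene's retinal image of a
#' Snellen E is identified correctly. Identification scores the rendered
#' image against the four diffraction-limited orientation templates with a
#' contrast-retaining matched filter (regression slope of image on
#' template); the true orientation must score highest and beat the runner-up
#' by at least `margin`. Returns 1.3 when never met.
#'
#' @param session a [refraction_session()] (or any scene accepted by
#'   [scene_psf()]).
#' @param extra_sphere additional sphere (D) applied at the pupil plane.
#' @param orientations E orientations that must all be identified
#'   (default `c(0, 90)`).
#' @param margin required NCC margin over the runner-up (default 0.02).
#' @param grid_logmar the search grid (default `seq(-0.3, 1.3, 0.1)`).
#' @param start search hint; the scan walks down/up from here assuming
#'   identification is monotone in letter size.
#' @return estimated acuity in logMAR.
#' @export
estimate_va <- function(session, extra_sphere = 0, orientations = c(0, 90),
                        margin = 0.02, grid_logmar = seq(-0.3, 1.3, 0.1),
                        start = 0.4) {
  psf <- scene_psf(session, extra_sphere = extra_sphere)
  grid_logmar <- round(sort(grid_logmar), 10)
  identify_ok <- function(L) {
    for (orient in orientations) {
      ch <- make_snellen_e(L, orient, pixel_scale = psf$pixel_scale)
      img <- render_retinal_image(ch, psf)
      sc <- vapply(c(0, 90, 180, 270), function(o)
        template_match(img$image,
                       acuity_template(session$grid, L, o)$image), numeric(1))
      best <- which.max(sc)
      if (c(0, 90, 180, 270)[best] != orient) return(FALSE)
      if (sc[best] - max(sc[-best]) < margin) return(FALSE)
    }
    TRUE
  }
  i <- which.min(abs(grid_logmar - start))
  if (identify_ok(grid_logmar[i])) {
    while (i > 1 && identify_ok(grid_logmar[i - 1])) i <- i - 1
    return(grid_logmar[i])
  }
  while (i < length(grid_logmar)) {
    i <- i + 1
    if (identify_ok(grid_logmar[i])) return(grid_logmar[i])
  }
  max(grid_logmar)
}

#' Through-focus (defocus) curve of a scene
#'
#' Adds a virtual sphere of each listed power at the pupil plane, computes
#' the Visual Strehl ratio of the resulting scene, and optionally the
#' estimated visual acuity. Characterizes multifocal corrections: with a
#' centre-near +2.00 D add design the curve is bimodal with peaks near 0 D
#' (distance zones) and -2 D (near zones) of object vergence.
#'
#' @param session a [refraction_session()].
#' @param defocus_grid numeric vector of added sphere powers in D
#'   (strictly increasing recommended).
#' @param compute_va logical: also estimate acuity at each point (slow).
#' @return An object of class `defocus_curve`: data.frame with columns
#'   `defocus_D`, `vs`, `va_logmar`.
#' @export
defocus_curve <- function(session, defocus_grid = seq(-3, 1, 0.25),
                          compute_va = FALSE) {
  stopifnot(all(is.finite(defocus_grid)))
  rows <- lapply(defocus_grid, function(d) {
    vs <- visual_strehl_psf(scene_psf(session, extra_sphere = d))
    va <- if (compute_va) estimate_va(session, extra_sphere = d) else NA_real_
    data.frame(defocus_D = d, vs = vs, va_logmar = va)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("defocus_curve", class(out))
  out
}

#' Write a through-focus image montage to PNG
#'
#' Renders the scene's retinal image of a Snellen E at each defocus value
#' and concatenates them left (most distant object) to right into a single
#' strip; the companion per-image Visual Strehl values are returned
#' invisibly (and are also available via [defocus_curve()]).
#'
#' @param session a [refraction_session()].
#' @param path output PNG path.
#' @param defocus_grid added sphere powers in D, one column per value.
#' @param logmar letter size of the E (default 0).
#' @return invisibly, the Visual Strehl value under each column.
#' @export
write_through_focus_montage <- function(session, path,
                                        defocus_grid = seq(0, -3, -0.5),
                                        logmar = 0) {
  panes <- lapply(defocus_grid, function(d) {
    psf <- scene_psf(session, extra_sphere = d)
    ch <- make_snellen_e(logmar, 0, pixel_scale = psf$pixel_scale)
    list(img = render_retinal_image(ch, psf)$image,
         vs = visual_strehl_psf(psf))
  })
  h <- max(vapply(panes, function(p) nrow(p$img), integer(1)))
  strip <- do.call(cbind, lapply(panes, function(p) {
    img <- pmin(pmax(p$img, 0), 1)
    if (nrow(img) < h) img <- rbind(img, matrix(1, h - nrow(img), ncol(img)))
    cbind(img, matrix(0.5, h, 2))     # thin separator
  }))
  png::writePNG(strip, target = path)
  invisible(stats::setNames(vapply(panes, function(p) p$vs, numeric(1)),
                            defocus_grid))
}

#' Export a defocus curve to CSV
#' @param curve a [defocus_curve()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_defocus_curve <- function(curve, path) {
  utils::write.csv(as.data.frame(curve)[c("defocus_D", "vs", "va_logmar")],
                   path, row.names = FALSE)
  invisible(path)
}
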