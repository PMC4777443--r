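# Programmatic optotype charts with exact angular geometry. Charts are
# grayscale luminance rasters (background 1 = white, ink 0 = black) tagged
# with their arcmin-per-pixel scale. Glyphs come from a built-in 5x5-cell
# bitmap font (Sloan-style stroke geometry: stroke width = 1/5 of letter
# height), so no system font is ever touched and rasters are reproducible
# bit-exactly.

glyph_rows <- list(
  A = c(".###.", "#...#", "#####", "#...#", "#...#"),
  C = c(".####", "#....", "#....", "#....", ".####"),
  D = c("####.", "#...#", "#...#", "#...#", "####."),
  E = c("#####", "#....", "#####", "#....", "#####"),
  F = c("#####", "#....", "####.", "#....", "#...."),
  H = c("#...#", "#...#", "#####", "#...#", "#...#"),
  K = c("#...#", "#..#.", "###..", "#..#.", "#...#"),
  L = c("#....", "#....", "#....", "#....", "#####"),
  N = c("#...#", "##..#", "#.#.#", "#..##", "#...#"),
  O = c(".###.", "#...#", "#...#", "#...#", ".###."),
  P = c("####.", "#...#", "####.", "#....", "#...."),
  R = c("####.", "#...#", "####.", "#..#.", "#...#"),
  S = c(".####", "#....", ".###.", "....#", "####."),
  T = c("#####", "..#..", "..#..", "..#..", "..#.."),
  U = c("#...#", "#...#", "#...#", "#...#", ".###."),
  V = c("#...#", "#...#", "#...#", ".#.#.", "..#.."),
  Z = c("#####", "...#.", "..#..", ".#...", "#####")
)

glyph_matrix <- function(ch) {
  rows <- glyph_rows[[toupper(ch)]]
  if (is.null(rows)) stop("no glyph for character '", ch, "'")
  do.call(rbind, lapply(rows, function(r) as.integer(strsplit(r, "")[[1]] == "#")))
}

# Nearest-neighbour upscale of a cell bitmap to h x w pixels.
scale_bitmap <- function(bm, h, w) {
  ri <- pmin(nrow(bm), pmax(1L, ceiling(seq_len(h) * nrow(bm) / h)))
  ci <- pmin(ncol(bm), pmax(1L, ceiling(seq_len(w) * ncol(bm) / w)))
  bm[ri, ci, drop = FALSE]
}

#' Optotype chart container
#'
#' @param image luminance matrix in `[0, 1]` (1 = white background, 0 = ink).
#' @param pixel_scale arcmin per pixel (> 0).
#' @param kind one of `"letter_line"`, `"single_letter"`, `"snellen_e"`,
#'   `"clock_dial"`, `"dot_pattern"`, `"custom"`.
#' @param logmar letter size in logMAR, or NA for non-letter charts. Letter
#'   height in arcmin is `5 * 10^logmar`.
#' @param angular_size overall ink extent in arcmin.
#' @param background background luminance (default 1).
#' @return An object of class `chart`.
#' @export
chart <- function(image, pixel_scale, kind = "custom", logmar = NA_real_,
                  angular_size = NA_real_, background = 1) {
  stopifnot(is.matrix(image), pixel_scale > 0)
  structure(list(image = image, pixel_scale = pixel_scale, kind = kind,
                 logmar = logmar, angular_size = angular_size,
                 background = background),
            class = "chart")
}

#' @export
print.chart <- function(x, ...) {
  cat(sprintf("<chart:%s> %dx%d px @ %.4g arcmin/px (%.4g x %.4g arcmin)%s\n",
              x$kind, nrow(x$image), ncol(x$image), x$pixel_scale,
              nrow(x$image) * x$pixel_scale, ncol(x$image) * x$pixel_scale,
              if (is.finite(x$logmar)) sprintf(", %.2f logMAR", x$logmar) else ""))
  invisible(x)
}

letter_height_px <- function(logmar, pixel_scale) {
  max(5L, as.integer(round(5 * 10^logmar / pixel_scale)))
}

#' Line of letters at a given logMAR size
#'
#' Each letter subtends `5 * 10^logmar` arcmin in height (1-arcmin stroke at
#' 0 logMAR), the inter-letter gap is one letter width, and the stroke width
#' is one fifth of the height.
#'
#' @param logmar letter size in logMAR.
#' @param letters character string of glyphs to render (built-in font; see
#'   `refractsim:::glyph_rows` for the available set).
#' @param pixel_scale arcmin per pixel (default 0.125, i.e. 8 px per arcmin).
#' @param margin white margin around the line, arcmin (default 2.5).
#' @return a [chart()] of kind `"letter_line"` (or `"single_letter"`).
#' @export
make_letter_line <- function(logmar, letters = "NCKZO", pixel_scale = 0.125,
                             margin = 2.5) {
  chars <- strsplit(letters, "")[[1]]
  if (!length(chars)) stop("letters must contain at least one character")
  h <- letter_height_px(logmar, pixel_scale)
  m <- as.integer(round(margin / pixel_scale))
  glyphs <- lapply(chars, function(ch) scale_bitmap(glyph_matrix(ch), h, h))
  gap <- matrix(0L, h, h)
  row <- glyphs[[1]]
  for (g in glyphs[-1]) row <- cbind(row, gap, g)
  ink <- rbind(matrix(0L, m, ncol(row) + 2 * m),
               cbind(matrix(0L, h, m), row, matrix(0L, h, m)),
               matrix(0L, m, ncol(row) + 2 * m))
  chart(1 - ink, pixel_scale,
        kind = if (length(chars) == 1) "single_letter" else "letter_line",
        logmar = logmar, angular_size = h * pixel_scale)
}

# clockwise quarter-turn rotations
rotate_quarter <- function(m, k) {
  k <- k %% 4
  for (i in seq_len(k)) m <- t(m[nrow(m):1, , drop = FALSE])
  m
}

#' Snellen/tumbling E optotype
#'
#' Standard 5x5-cell E with 1/5-height strokes; orientation by exact
#' quarter-turn rotations. Orientation 0 has the limbs pointing right.
#'
#' @param logmar letter size in logMAR (height `5 * 10^logmar` arcmin).
#' @param orientation one of 0, 90, 180, 270 degrees.
#' @param pixel_scale arcmin per pixel (default 0.125).
#' @param margin white margin in arcmin (default 2.5).
#' @return a [chart()] of kind `"snellen_e"`.
#' @export
make_snellen_e <- function(logmar = 0, orientation = 0, pixel_scale = 0.125,
                           margin = 2.5) {
  if (!orientation %in% c(0, 90, 180, 270))
    stop("orientation must be one of 0, 90, 180, 270")
  # base glyph: spine on the left, limbs pointing right
  base <- do.call(rbind, lapply(
    c("#####", "#....", "#####", "#....", "#####"),
    function(r) as.integer(strsplit(r, "")[[1]] == "#")))
  bm <- rotate_quarter(base, orientation / 90)
  h <- letter_height_px(logmar, pixel_scale)
  m <- as.integer(round(margin / pixel_scale))
  ink <- scale_bitmap(bm, h, h)
  ink <- rbind(matrix(0L, m, h + 2 * m),
               cbind(matrix(0L, h, m), ink, matrix(0L, h, m)),
               matrix(0L, m, h + 2 * m))
  ch <- chart(1 - ink, pixel_scale, kind = "snellen_e", logmar = logmar,
              angular_size = h * pixel_scale)
  ch$orientation <- orientation
  ch
}

#' Astigmatic clock-dial chart
#'
#' Circular fan chart with 12 radii at 30-degree intervals and an overall
#' diameter of 250 arcmin.
#'
#' @param pixel_scale arcmin per pixel (default 0.25).
#' @param diameter overall angular size in arcmin (default 250).
#' @param line_width spoke width in arcmin (default 5).
#' @param inner_frac central gap as a fraction of the outer radius
#'   (default 0.2).
#' @param margin white margin in arcmin (default 10).
#' @return a [chart()] of kind `"clock_dial"`.
#' @export
make_clock_dial <- function(pixel_scale = 0.25, diameter = 250,
                            line_width = 5, inner_frac = 0.2, margin = 10) {
  r_out <- diameter / 2
  r_in <- inner_frac * r_out
  half <- r_out + margin
  n <- 2L * as.integer(round(half / pixel_scale)) + 1L
  ax <- (seq_len(n) - (n + 1) / 2) * pixel_scale
  X <- matrix(rep(ax, each = n), n, n)   # x along columns
  Y <- matrix(rep(rev(ax), times = n), n, n)  # y up along rows
  ink <- matrix(FALSE, n, n)
  for (k in 0:11) {
    phi <- k * 30 * pi / 180
    s <- X * cos(phi) + Y * sin(phi)          # along-spoke coordinate
    d <- abs(-X * sin(phi) + Y * cos(phi))    # transverse distance
    ink <- ink | (s >= r_in & s <= r_out & d <= line_width / 2)
  }
  ch <- chart(1 - ink, pixel_scale, kind = "clock_dial",
              angular_size = diameter)
  ch$dial <- list(r_in = r_in, r_out = r_out, line_width = line_width)
  ch
}

#' Dot-pattern chart
#'
#' Square grid of circular dots; the overall ink extent (outer dot edges) is
#' `extent` arcmin.
#'
#' @param pixel_scale arcmin per pixel (default 0.125).
#' @param extent overall angular size in arcmin (default 50).
#' @param n_dots dots per side (default 5).
#' @param dot_diameter dot diameter in arcmin (default 2).
#' @param margin white margin in arcmin (default 5).
#' @return a [chart()] of kind `"dot_pattern"`.
#' @export
make_dot_pattern <- function(pixel_scale = 0.125, extent = 50, n_dots = 5,
                             dot_diameter = 2, margin = 5) {
  stopifnot(n_dots >= 2, dot_diameter > 0, extent > dot_diameter)
  spacing <- (extent - dot_diameter) / (n_dots - 1)
  centers <- (seq_len(n_dots) - (n_dots + 1) / 2) * spacing
  half <- extent / 2 + margin
  n <- 2L * as.integer(round(half / pixel_scale)) + 1L
  ax <- (seq_len(n) - (n + 1) / 2) * pixel_scale
  X <- matrix(rep(ax, each = n), n, n)
  Y <- matrix(rep(rev(ax), times = n), n, n)
  ink <- matrix(FALSE, n, n)
  rad <- dot_diameter / 2
  for (cx in centers) for (cy in centers)
    ink <- ink | ((X - cx)^2 + (Y - cy)^2 <= rad^2)
  chart(1 - ink, pixel_scale, kind = "dot_pattern", angular_size = extent)
}
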