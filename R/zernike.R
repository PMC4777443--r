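# Zernike polynomial algebra in the OSA/ANSI single-index convention with
# orthonormal normalization: <Z_j, Z_k> = delta_jk over the unit disc, so the
# total wavefront variance is the sum of squared coefficients.

#' Convert OSA single indices to (n, m) radial/azimuthal orders
#'
#' @param j integer vector of OSA single indices (>= 0).
#' @return A list with integer vectors `n` (radial order) and `m` (signed
#'   azimuthal frequency), such that `j = (n*(n+2) + m)/2`.
#' @export
osa_to_nm <- function(j) {
  j <- as.integer(j)
  if (any(j < 0)) stop("OSA indices must be non-negative integers")
  n <- as.integer(ceiling((-3 + sqrt(9 + 8 * j)) / 2))
  m <- as.integer(2L * j - n * (n + 2L))
  list(n = n, m = m)
}

#' Convert (n, m) orders to the OSA single index
#'
#' @param n radial order (>= 0).
#' @param m signed azimuthal frequency; `n - |m|` must be even and `|m| <= n`.
#' @return integer OSA index.
#' @export
nm_to_osa <- function(n, m) {
  if (any(abs(m) > n) || any((n - abs(m)) %% 2 != 0))
    stop("invalid (n, m) pair: need |m| <= n and n - |m| even")
  as.integer((n * (n + 2) + m) / 2)
}

#' Zernike coefficient set bound to a measurement pupil
#'
#' Bundles OSA-indexed wavefront coefficients (micrometres) with the pupil
#' radius over which they were fitted. Absent indices read as zero.
#'
#' @param coeffs numeric vector of coefficients in micrometres. If named, the
#'   names are OSA indices; if unnamed, positions map to OSA indices
#'   `0, 1, 2, ...`.
#' @param pupil_radius pupil radius in mm (> 0).
#' @param source_label free-text provenance tag.
#' @return An object of class `zernike_coefficients`: a dense numeric vector
#'   over OSA indices `0..jmax` plus `pupil_radius` and `source_label`.
#' @export
zernike_coefficients <- function(coeffs, pupil_radius, source_label = "") {
  if (!is.numeric(pupil_radius) || length(pupil_radius) != 1 ||
      !is.finite(pupil_radius) || pupil_radius <= 0)
    stop("pupil_radius must be a single positive number (mm)")
  coeffs <- coeffs[!is.na(coeffs)]
  if (is.null(names(coeffs))) {
    j <- seq_along(coeffs) - 1L
  } else {
    j <- suppressWarnings(as.integer(names(coeffs)))
    if (any(is.na(j)) || any(j < 0))
      stop("coefficient names must be non-negative integer OSA indices")
  }
  jmax <- if (length(j)) max(j) else 0L
  dense <- numeric(jmax + 1L)
  dense[j + 1L] <- as.numeric(coeffs)
  structure(
    list(coeffs = dense, pupil_radius = pupil_radius,
         source_label = as.character(source_label)),
    class = "zernike_coefficients")
}

#' @export
print.zernike_coefficients <- function(x, ...) {
  nz <- which(x$coeffs != 0) - 1L
  cat(sprintf("<zernike_coefficients> %d term(s), pupil radius %.3g mm%s\n",
              length(nz), x$pupil_radius,
              if (nzchar(x$source_label)) paste0(" [", x$source_label, "]") else ""))
  if (length(nz)) {
    nm <- osa_to_nm(nz)
    df <- data.frame(j = nz, n = nm$n, m = nm$m,
                     coefficient_um = x$coeffs[nz + 1L])
    print(df, row.names = FALSE)
  }
  invisible(x)
}

#' Read a coefficient by OSA index (0 when absent)
#' @param z a `zernike_coefficients` object.
#' @param j integer OSA index vector.
#' @return numeric vector of coefficients (micrometres).
#' @export
zernike_get <- function(z, j) {
  stopifnot(inherits(z, "zernike_coefficients"))
  j <- as.integer(j)
  out <- numeric(length(j))
  inside <- j < length(z$coeffs)
  out[inside] <- z$coeffs[j[inside] + 1L]
  out
}

# Radial polynomial R_n^{|m|}(rho), unnormalized, via the factorial series.
zernike_radial <- function(n, m, rho) {
  m <- abs(m)
  out <- numeric(length(rho))
  for (k in 0:((n - m) / 2)) {
    ck <- (-1)^k * factorial(n - k) /
      (factorial(k) * factorial((n + m) / 2 - k) * factorial((n - m) / 2 - k))
    out <- out + ck * rho^(n - 2 * k)
  }
  out
}

#' Evaluate a single orthonormal Zernike polynomial
#'
#' @param j OSA single index.
#' @param rho normalized radius in `[0, 1]`.
#' @param theta azimuth in radians, counterclockwise from +x.
#' @return numeric vector of polynomial values.
#' @export
zernike_poly <- function(j, rho, theta) {
  nm <- osa_to_nm(j)
  n <- nm$n; m <- nm$m
  norm <- sqrt(2 * (n + 1) / (1 + (m == 0)))
  rad <- zernike_radial(n, m, rho)
  if (m > 0) norm * rad * cos(m * theta)
  else if (m < 0) norm * rad * sin(-m * theta)
  else norm * rad
}

#' Synthesize a wavefront map from Zernike coefficients
#'
#' Computes `W(x, y) = sum_j c_j Z_j(rho, theta)` on the pupil sampling of a
#' [grid_spec()], with `rho = r / pupil_radius`. Values outside the pupil mask
#' are zero.
#'
#' @param z a `zernike_coefficients` object.
#' @param grid a [grid_spec()]; its physical half-width must reach
#'   `z$pupil_radius`.
#' @param include_modes optional integer vector of OSA indices to include
#'   (default: all present).
#' @return A `wavefront_map`: list with `values` (micrometre matrix,
#'   `n_pupil x n_pupil`), `mask` (logical), and `grid`.
#' @export
evaluate_wavefront <- function(z, grid, include_modes = NULL) {
  stopifnot(inherits(z, "zernike_coefficients"), inherits(grid, "grid_spec"))
  if (grid$pupil_radius + 1e-9 < z$pupil_radius)
    stop("grid half-width is smaller than the coefficient pupil radius; ",
         "rescale the coefficients first")
  xy <- grid_coords(grid)
  r <- sqrt(outer(xy$y^2, xy$x^2, "+"))
  theta <- atan2(outer(xy$y, rep(1, length(xy$x))),
                 outer(rep(1, length(xy$y)), xy$x))
  mask <- r <= z$pupil_radius + 1e-12
  rho <- pmin(r / z$pupil_radius, 1)
  values <- matrix(0, nrow(r), ncol(r))
  idx <- which(z$coeffs != 0) - 1L
  if (!is.null(include_modes)) idx <- intersect(idx, as.integer(include_modes))
  for (j in idx) {
    values <- values + z$coeffs[j + 1L] * zernike_poly(j, rho, theta)
  }
  values[!mask] <- 0
  structure(list(values = values, mask = mask, grid = grid),
            class = "wavefront_map")
}

#' Zero wavefront map on a grid
#' @param grid a [grid_spec()].
#' @return a `wavefront_map` of zeros with the grid's pupil mask.
#' @export
zero_wavefront <- function(grid) {
  xy <- grid_coords(grid)
  r <- sqrt(outer(xy$y^2, xy$x^2, "+"))
  mask <- r <= grid$pupil_radius + 1e-12
  structure(list(values = matrix(0, nrow(r), ncol(r)), mask = mask,
                 grid = grid),
            class = "wavefront_map")
}

#' Add two wavefront maps defined on the same grid
#' @param a,b `wavefront_map` objects sharing one grid.
#' @return their pointwise sum (mask intersection).
#' @export
add_wavefronts <- function(a, b) {
  stopifnot(inherits(a, "wavefront_map"), inherits(b, "wavefront_map"))
  if (!isTRUE(all.equal(a$grid[c("n_pupil", "pupil_radius", "wavelength")],
                        b$grid[c("n_pupil", "pupil_radius", "wavelength")])))
    stop("wavefront maps live on different grids")
  structure(list(values = a$values + b$values, mask = a$mask & b$mask,
                 grid = a$grid),
            class = "wavefront_map")
}

#' Rescale Zernike coefficients to a smaller pupil radius
#'
#' Returns the coefficient set that reproduces the original wavefront exactly
#' on the concentric sub-pupil of radius `new_radius`. The transform is
#' analytic: within each azimuthal family the radial polynomials are expanded
#' in monomials, the radial scaling `rho -> eps * rho` is applied, and the
#' result is projected back (triangular system, no sampling involved).
#' Up-scaling is an extrapolation and is rejected.
#'
#' @param z a `zernike_coefficients` object.
#' @param new_radius target pupil radius in mm, `0 < new_radius <= pupil_radius`.
#' @return a `zernike_coefficients` object at `new_radius`.
#' @export
rescale_coefficients <- function(z, new_radius) {
  stopifnot(inherits(z, "zernike_coefficients"))
  if (!is.numeric(new_radius) || length(new_radius) != 1 || new_radius <= 0)
    stop("new_radius must be a single positive number (mm)")
  if (new_radius > z$pupil_radius + 1e-12)
    stop("cannot rescale to a larger pupil: coefficients are only valid ",
         "inside their measurement pupil")
  eps <- new_radius / z$pupil_radius
  jmax <- length(z$coeffs) - 1L
  nm <- osa_to_nm(0:jmax)
  nmax <- max(nm$n)
  out <- numeric(jmax + 1L)
  for (m in unique(nm$m)) {
    ns <- seq(abs(m), nmax, by = 2L)          # radial orders in this family
    ns <- ns[nm_to_osa(ns, rep(m, length(ns))) <= jmax]
    js <- nm_to_osa(ns, rep(m, length(ns)))
    cvec <- z$coeffs[js + 1L]
    if (all(cvec == 0)) next
    # A[i, k]: monomial expansion N R_n^{|m|} = sum_p a_p rho^p, p = |m|, |m|+2, ...
    pows <- seq(abs(m), max(ns), by = 2L)
    A <- matrix(0, length(ns), length(pows))
    for (i in seq_along(ns)) {
      n <- ns[i]
      norm <- sqrt(2 * (n + 1) / (1 + (m == 0)))
      for (k in 0:((n - abs(m)) / 2)) {
        p <- n - 2L * k
        ck <- (-1)^k * factorial(n - k) /
          (factorial(k) * factorial((n + abs(m)) / 2 - k) *
             factorial((n - abs(m)) / 2 - k))
        A[i, match(p, pows)] <- norm * ck
      }
    }
    mono <- as.vector(crossprod(A, cvec))     # monomial coefficients
    mono <- mono * eps^pows                   # rho -> eps * rho
    newc <- solve(t(A), mono)                 # back to Zernike basis
    out[js + 1L] <- newc
  }
  zernike_coefficients(stats::setNames(out, 0:jmax), new_radius,
                       source_label = z$source_label)
}

#' Root-mean-square wavefront error from a radial order upward
#'
#' With orthonormal Zernikes the RMS over the pupil is the Euclidean norm of
#' the included coefficients; `min_radial_order = 3` gives the conventional
#' higher-order RMS (RMS_HOA), `0` the total RMS including piston and tilt.
#'
#' @param z a `zernike_coefficients` object.
#' @param min_radial_order smallest radial order to include (>= 0).
#' @return RMS in micrometres.
#' @export
zernike_rms <- function(z, min_radial_order = 0) {
  stopifnot(inherits(z, "zernike_coefficients"))
  if (min_radial_order < 0) stop("min_radial_order must be >= 0")
  j <- seq_along(z$coeffs) - 1L
  keep <- osa_to_nm(j)$n >= min_radial_order
  sqrt(sum(z$coeffs[keep]^2))
}

#' Second-order Zernike terms equivalent to a sphero-cylindrical power
#'
#' Uses the power-vector decomposition `M = S + C/2`,
#' `J0 = -(C/2) cos 2a`, `J45 = -(C/2) sin 2a` and the quadratic wavefront
#' `W = -1/2 (M r^2 + J0 (x^2 - y^2) + 2 J45 xy)`; with radii in mm and powers
#' in dioptres the coefficients come out directly in micrometres:
#' `c(2,0) = -M R^2 / (4 sqrt 3)`, `c(2,+2) = -J0 R^2 / (2 sqrt 6)`,
#' `c(2,-2) = -J45 R^2 / (2 sqrt 6)`. Under this sign convention a myopic eye
#' (corrected by minus sphere) carries positive defocus `c(2,0)`.
#'
#' @param sc a [sphero_cylinder()].
#' @param pupil_radius pupil radius in mm.
#' @return a `zernike_coefficients` object with only second-order terms.
#' @export
sphero_cylinder_to_zernike <- function(sc, pupil_radius) {
  sc <- as_sphero_cylinder(sc)
  pv <- power_vector(sc)
  R2 <- pupil_radius^2
  co <- c("3" = -pv[["J45"]] * R2 / (2 * sqrt(6)),   # j=3: Z2^-2
          "4" = -pv[["M"]]  * R2 / (4 * sqrt(3)),    # j=4: Z2^0
          "5" = -pv[["J0"]] * R2 / (2 * sqrt(6)))    # j=5: Z2^+2
  zernike_coefficients(co, pupil_radius)
}

#' Sphero-cylindrical power equivalent to second-order Zernike terms
#'
#' Exact inverse of [sphero_cylinder_to_zernike()] on the second-order
#' subspace; reported in minus-cylinder form with axis in `[0, 180)` degrees.
#'
#' @param z a `zernike_coefficients` object (only `j = 3, 4, 5` are read).
#' @return a [sphero_cylinder()].
#' @export
zernike_to_sphero_cylinder <- function(z) {
  stopifnot(inherits(z, "zernike_coefficients"))
  R2 <- z$pupil_radius^2
  M   <- -4 * sqrt(3) * zernike_get(z, 4) / R2
  J0  <- -2 * sqrt(6) * zernike_get(z, 5) / R2
  J45 <- -2 * sqrt(6) * zernike_get(z, 3) / R2
  power_vector_to_sc(M, J0, J45)
}
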