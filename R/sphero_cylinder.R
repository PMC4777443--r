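# Sphero-cylindrical prescriptions and their power-vector form.
# Conventions: minus-cylinder canonical form; TABO axis in degrees,
# counterclockwise from horizontal, stored in [0, 180) and displayed with
# 0 shown as 180 (clinical usage).

#' Sphero-cylindrical lens power
#'
#' @param sphere sphere power S in dioptres.
#' @param cylinder cylinder power C in dioptres; plus-cylinder input is
#'   transposed to the canonical minus-cylinder form.
#' @param axis cylinder axis in degrees (TABO); ignored when `cylinder = 0`.
#' @return An object of class `sphero_cylinder` with elements `sphere`,
#'   `cylinder` (<= 0) and `axis` in `[0, 180)`.
#' @export
sphero_cylinder <- function(sphere = 0, cylinder = 0, axis = 0) {
  stopifnot(is.numeric(sphere), is.numeric(cylinder), is.numeric(axis))
  if (cylinder > 0) {          # transpose to minus-cylinder form
    sphere <- sphere + cylinder
    cylinder <- -cylinder
    axis <- axis + 90
  }
  axis <- axis %% 180
  if (cylinder == 0) axis <- 0
  structure(list(sphere = sphere, cylinder = cylinder, axis = axis),
            class = "sphero_cylinder")
}

as_sphero_cylinder <- function(x) {
  if (inherits(x, "sphero_cylinder")) return(x)
  if (is.numeric(x) && length(x) == 3)
    return(sphero_cylinder(x[[1]], x[[2]], x[[3]]))
  stop("cannot interpret input as a sphero_cylinder")
}

#' Display axis: clinical convention, 0 deg reported as 180
#' @param axis_deg numeric axis in `[0, 180)`.
#' @return axis in `(0, 180]`.
#' @export
clinical_axis <- function(axis_deg) {
  a <- axis_deg %% 180
  ifelse(a == 0, 180, a)
}

#' @export
print.sphero_cylinder <- function(x, ...) {
  if (x$cylinder == 0)
    cat(sprintf("%+.2f DS\n", x$sphere))
  else
    cat(sprintf("%+.2f %+.2f x %g\n", x$sphere, x$cylinder,
                clinical_axis(x$axis)))
  invisible(x)
}

#' Power-vector (M, J0, J45) form of a sphero-cylinder
#'
#' `M = S + C/2` (spherical equivalent), `J0 = -(C/2) cos 2a`,
#' `J45 = -(C/2) sin 2a`. Power vectors add under thin-lens stacking.
#'
#' @param sc a [sphero_cylinder()].
#' @return named numeric vector `c(M, J0, J45)` in dioptres.
#' @export
power_vector <- function(sc) {
  sc <- as_sphero_cylinder(sc)
  a <- sc$axis * pi / 180
  c(M = sc$sphere + sc$cylinder / 2,
    J0 = -(sc$cylinder / 2) * cos(2 * a),
    J45 = -(sc$cylinder / 2) * sin(2 * a))
}

#' Sphero-cylinder from power-vector components
#'
#' @param M spherical equivalent (D).
#' @param J0,J45 crossed-cylinder components (D).
#' @return a [sphero_cylinder()] in minus-cylinder form.
#' @export
power_vector_to_sc <- function(M, J0, J45) {
  half_c <- sqrt(J0^2 + J45^2)
  C <- -2 * half_c
  S <- M - C / 2
  axis <- if (half_c > 0) (atan2(J45, J0) / 2 * 180 / pi) %% 180 else 0
  sphero_cylinder(S, C, axis)
}

#' Sum of sphero-cylinders (power-vector addition)
#' @param ... [sphero_cylinder()] objects (or S/C/axis triples).
#' @return a single combined [sphero_cylinder()].
#' @export
combine_sphero_cylinders <- function(...) {
  scs <- lapply(list(...), as_sphero_cylinder)
  if (!length(scs)) return(sphero_cylinder())
  pv <- rowSums(vapply(scs, power_vector, numeric(3)))
  power_vector_to_sc(pv[["M"]], pv[["J0"]], pv[["J45"]])
}

#' Meridional (curvital) power of a sphero-cylinder
#' @param sc a [sphero_cylinder()].
#' @param meridian_deg meridian direction in degrees.
#' @return power in dioptres along that meridian: `S + C sin^2(meridian - axis)`.
#' @export
meridional_power <- function(sc, meridian_deg) {
  sc <- as_sphero_cylinder(sc)
  sc$sphere + sc$cylinder * sin((meridian_deg - sc$axis) * pi / 180)^2
}
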