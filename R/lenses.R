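# The optical scene: reduced schematic eye, virtual phoropter (thin-lens
# stack with vertex-plane power transposition), Jackson Cross Cylinder, and
# concentric-ring multifocal contact lenses. All phase contributions are
# expressed at the eye's exit-pupil plane and summed:
#   W_T = W_eye + W_lens + [W_JCC * S] (+ W_CL)

#' Reduced schematic eye with patient aberrometry
#'
#' @param aberrometry a [zernike_coefficients()] object (the eye's wavefront
#'   error over its measurement pupil).
#' @param pupil_radius entrance-pupil radius in mm used for simulation; must
#'   not exceed the aberrometry measurement radius (coefficients are rescaled
#'   down, never extrapolated up).
#' @param focal_length eye focal length in mm (default 22.4).
#' @param refractive_index ocular refractive index (default 1.33).
#' @param wavelength wavelength in nm (default 587).
#' @return An object of class `schematic_eye`; its aberrometry is already
#'   rescaled to `pupil_radius`.
#' @export
schematic_eye <- function(aberrometry, pupil_radius = NULL,
                          focal_length = 22.4, refractive_index = 1.33,
                          wavelength = 587) {
  stopifnot(inherits(aberrometry, "zernike_coefficients"),
            focal_length > 0, wavelength > 0)
  if (is.null(pupil_radius)) pupil_radius <- aberrometry$pupil_radius
  if (pupil_radius > aberrometry$pupil_radius + 1e-12)
    stop("simulation pupil radius exceeds the aberrometry measurement pupil")
  ab <- if (pupil_radius < aberrometry$pupil_radius)
    rescale_coefficients(aberrometry, pupil_radius) else aberrometry
  structure(list(aberrometry = ab, pupil_radius = pupil_radius,
                 focal_length = focal_length,
                 refractive_index = refractive_index,
                 wavelength = wavelength),
            class = "schematic_eye")
}

#' Virtual phoropter: a stack of thin sphero-cylindrical lenses
#'
#' @param lenses list of [sphero_cylinder()] objects (may be empty).
#' @param vertex_distance distance from the phoropter plane to the entrance
#'   pupil, in mm (>= 0). Default 15 mm: a 12 mm spectacle vertex plus about
#'   3 mm from cornea to entrance pupil.
#' @return An object of class `phoropter_state`.
#' @export
phoropter_state <- function(lenses = list(), vertex_distance = 15) {
  stopifnot(vertex_distance >= 0)
  lenses <- lapply(lenses, as_sphero_cylinder)
  structure(list(lenses = lenses, vertex_distance = vertex_distance),
            class = "phoropter_state")
}

#' Combined trial correction of a phoropter stack (at the phoropter plane)
#' @param ph a [phoropter_state()].
#' @return a [sphero_cylinder()]: the power-vector sum of the stack.
#' @export
phoropter_trial <- function(ph) {
  stopifnot(inherits(ph, "phoropter_state"))
  do.call(combine_sphero_cylinders, ph$lenses)
}

#' Jackson Cross Cylinder state
#'
#' A cross cylinder of power `+/-P` is the combination of a `+P` and a `-P`
#' cylinder with perpendicular axes; its sphero-cylindrical equivalent is
#' `S = +P, C = -2P` with the minus-cylinder axis at `axis` (plus 90 degrees
#' when flipped). Its spherical equivalent M is exactly zero.
#'
#' @param power the P magnitude in dioptres (> 0, default 0.50).
#' @param axis minus-cylinder axis in degrees when unflipped.
#' @param flipped logical; flipping rotates the minus axis by 90 degrees.
#' @param active logical; an inactive JCC contributes zero phase.
#' @param mode `"axis-search"` or `"power-search"` (procedure bookkeeping).
#' @return An object of class `jcc_state`.
#' @export
jcc_state <- function(power = 0.50, axis = 0, flipped = FALSE, active = TRUE,
                      mode = c("axis-search", "power-search")) {
  stopifnot(power > 0)
  mode <- match.arg(mode)
  structure(list(power = power, axis = axis %% 180, flipped = isTRUE(flipped),
                 active = isTRUE(active), mode = mode),
            class = "jcc_state")
}

#' Flip a Jackson Cross Cylinder
#'
#' Toggles the flip state; two flips restore the original state (and hence
#' the original phase map bit-exactly).
#' @param j a [jcc_state()].
#' @return the flipped `jcc_state`.
#' @export
jcc_flip <- function(j) {
  stopifnot(inherits(j, "jcc_state"))
  j$flipped <- !j$flipped
  j
}

#' Sphero-cylindrical equivalent of a JCC state
#' @param j a [jcc_state()].
#' @return a [sphero_cylinder()] `(+P, -2P)` at the current minus axis.
#' @export
jcc_equivalent_sc <- function(j) {
  stopifnot(inherits(j, "jcc_state"))
  axis <- j$axis + if (j$flipped) 90 else 0
  sphero_cylinder(j$power, -2 * j$power, axis)
}

#' Concentric-ring multifocal contact lens design
#'
#' @param zones matrix or data.frame with columns `outer_radius` (mm, strictly
#'   increasing from the centre outward) and `add_power` (D).
#' @param label free-text design name.
#' @return An object of class `multifocal_design`.
#' @export
multifocal_design <- function(zones, label = "") {
  zones <- as.data.frame(zones)
  names(zones) <- c("outer_radius", "add_power")
  if (any(diff(zones$outer_radius) <= 0) || any(zones$outer_radius <= 0))
    stop("zone outer radii must be positive and strictly increasing")
  structure(list(zones = zones, label = as.character(label)),
            class = "multifocal_design")
}

#' Centre-near trifocal design: near, intermediate, distance rings
#'
#' Near (+2.00 D add) centre zone, +1.00 D intermediate annulus, plano
#' distance periphery. Ring radii are design defaults (0-1.5, 1.5-2.25,
#' 2.25-3.0 mm) and fully overridable.
#' @param radii numeric vector of the three outer radii in mm.
#' @param add near addition in D (default +2.00).
#' @param intermediate intermediate addition in D (default +1.00).
#' @return a [multifocal_design()].
#' @export
cl1_design <- function(radii = c(1.5, 2.25, 3.0), add = 2.00,
                       intermediate = 1.00) {
  multifocal_design(data.frame(outer_radius = radii,
                               add_power = c(add, intermediate, 0)),
                    label = "CL1 centre-near N/Int/D")
}

#' Centre-near bifocal design: alternating near/distance rings
#'
#' Near (+2.00 D add) centre, distance annulus, near periphery; no
#' intermediate-vision zone.
#' @param radii numeric vector of the three outer radii in mm.
#' @param add near addition in D (default +2.00).
#' @return a [multifocal_design()].
#' @export
cl2_design <- function(radii = c(1.5, 2.25, 3.0), add = 2.00) {
  multifocal_design(data.frame(outer_radius = radii,
                               add_power = c(add, 0, add)),
                    label = "CL2 centre-near N/D/N")
}

#' Effective power at the entrance-pupil plane
#'
#' Transposes a thin-lens power from the phoropter plane to the pupil plane a
#' distance `d_v` behind it: `F' = F / (1 - d_v * F)`. Applied per principal
#' meridian for sphero-cylinders.
#'
#' @param F lens power in dioptres (vectorized).
#' @param d_v vertex distance in metres.
#' @return transposed power in dioptres.
#' @export
effective_power_at_pupil <- function(F, d_v) {
  stopifnot(d_v >= 0)
  denom <- 1 - d_v * F
  if (any(abs(denom) < 1e-12))
    stop("lens focal point coincides with the pupil plane (1 - d_v * F = 0)")
  F / denom
}

#' Transpose a sphero-cylinder to the pupil plane
#'
#' Each principal power (`S` and `S + C`) is transposed independently via
#' [effective_power_at_pupil()]; the axis is unchanged.
#' @param sc a [sphero_cylinder()].
#' @param d_v vertex distance in metres.
#' @return the transposed [sphero_cylinder()].
#' @export
transpose_sphero_cylinder <- function(sc, d_v) {
  sc <- as_sphero_cylinder(sc)
  F1 <- effective_power_at_pupil(sc$sphere, d_v)
  F2 <- effective_power_at_pupil(sc$sphere + sc$cylinder, d_v)
  sphero_cylinder(F1, F2 - F1, sc$axis)
}

#' Spectacle magnification of a thin lens
#'
#' `SM = 1 / (1 - d_v * F)`: the apparent-size change introduced by a thin
#' lens of power `F` at vertex distance `d_v` from the entrance pupil. For a
#' sphero-cylinder the magnification is anamorphic and is computed per
#' principal meridian.
#'
#' @param F lens power in dioptres, or a [sphero_cylinder()].
#' @param d_v vertex distance in metres.
#' @return For scalar `F`, the scalar SM. For a sphero-cylinder, a list with
#'   `sm_axis` (magnification along the cylinder-axis direction, from power
#'   `S`), `sm_perp` (along the power meridian, from `S + C`) and
#'   `meridian_deg` (the axis direction).
#' @export
spectacle_magnification <- function(F, d_v) {
  stopifnot(d_v >= 0)
  if (inherits(F, "sphero_cylinder") ||
      (is.list(F) && !is.null(F$sphere))) {
    sc <- as_sphero_cylinder(F)
    list(sm_axis = spectacle_magnification(sc$sphere, d_v),
         sm_perp = spectacle_magnification(sc$sphere + sc$cylinder, d_v),
         meridian_deg = sc$axis)
  } else {
    denom <- 1 - d_v * F
    if (any(abs(denom) < 1e-12))
      stop("lens focal point coincides with the pupil plane (1 - d_v * F = 0)")
    1 / denom
  }
}

#' Anamorphic magnification of a whole phoropter stack
#'
#' Combines the stack into its power-vector sum and evaluates the anamorphic
#' spectacle magnification of that single equivalent thin lens at the stack's
#' vertex distance.
#' @param ph a [phoropter_state()].
#' @return as [spectacle_magnification()] for a sphero-cylinder.
#' @export
stack_magnification <- function(ph) {
  stopifnot(inherits(ph, "phoropter_state"))
  spectacle_magnification(phoropter_trial(ph), ph$vertex_distance * 1e-3)
}

# Quadratic wavefront (um) of a power vector over the pupil grid:
# W = -1/2 (M r^2 + J0 (x^2 - y^2) + 2 J45 x y), r in mm, powers in D.
quadratic_phase <- function(M, J0, J45, grid, pupil_radius) {
  xy <- grid_coords(grid)
  X <- outer(rep(1, length(xy$y)), xy$x)
  Y <- outer(xy$y, rep(1, length(xy$x)))
  r2 <- X^2 + Y^2
  mask <- r2 <= pupil_radius^2 + 1e-12
  values <- -0.5 * (M * r2 + J0 * (X^2 - Y^2) + 2 * J45 * X * Y)
  values[!mask] <- 0
  structure(list(values = values, mask = mask, grid = grid),
            class = "wavefront_map")
}

#' Phase of a phoropter lens at the pupil plane
#'
#' Transposes the thin lens to the pupil plane
#' ([transpose_sphero_cylinder()]) and evaluates its quadratic wavefront
#' there.
#'
#' @param sc a [sphero_cylinder()].
#' @param d_v vertex distance in metres.
#' @param grid a [grid_spec()].
#' @param pupil_radius pupil radius in mm defining the mask.
#' @return a `wavefront_map` in micrometres.
#' @export
lens_phase <- function(sc, d_v, grid, pupil_radius = grid$pupil_radius) {
  sct <- transpose_sphero_cylinder(sc, d_v)
  pv <- power_vector(sct)
  quadratic_phase(pv[["M"]], pv[["J0"]], pv[["J45"]], grid, pupil_radius)
}

#' Phase of a Jackson Cross Cylinder at the pupil plane
#'
#' The phase of the sphero-cylindrical equivalent of the current flip state,
#' transposed like any phoropter lens. An inactive JCC contributes the zero
#' map (the activation step function).
#'
#' @param j a [jcc_state()].
#' @inheritParams lens_phase
#' @return a `wavefront_map` in micrometres.
#' @export
jcc_phase <- function(j, d_v, grid, pupil_radius = grid$pupil_radius) {
  stopifnot(inherits(j, "jcc_state"))
  if (!j$active) return(zero_wavefront(grid))
  lens_phase(jcc_equivalent_sc(j), d_v, grid, pupil_radius)
}

#' Phase plate of a concentric-ring multifocal contact lens
#'
#' Inside each annulus the lens contributes the defocus phase of its add
#' power, `W = -add * r^2 / 2` (r in mm, W in um). The lens sits at the pupil
#' plane (no vertex transposition, no magnification) and must cover the whole
#' pupil. The profile is piecewise quadratic; discontinuities at ring
#' boundaries are permitted.
#'
#' @param design a [multifocal_design()].
#' @param grid a [grid_spec()].
#' @param pupil_radius pupil radius in mm; the outermost zone must reach it.
#' @return a `wavefront_map` in micrometres.
#' @export
multifocal_phase <- function(design, grid, pupil_radius = grid$pupil_radius) {
  stopifnot(inherits(design, "multifocal_design"))
  outer_r <- design$zones$outer_radius
  if (max(outer_r) + 1e-9 < pupil_radius)
    stop("contact-lens zones do not cover the pupil")
  xy <- grid_coords(grid)
  r2 <- outer(xy$y^2, xy$x^2, "+")
  r <- sqrt(r2)
  mask <- r <= pupil_radius + 1e-12
  values <- matrix(0, nrow(r), ncol(r))
  inner <- 0
  for (i in seq_len(nrow(design$zones))) {
    zone <- r >= inner & r < outer_r[i] + ifelse(i == nrow(design$zones), 1e-9, 0)
    values[zone] <- -0.5 * design$zones$add_power[i] * r2[zone]
    inner <- outer_r[i]
  }
  values[!mask] <- 0
  structure(list(values = values, mask = mask, grid = grid),
            class = "wavefront_map")
}

#' Total phase of the optical scene at the pupil plane
#'
#' Pointwise sum of the eye's aberrometry wavefront, every phoropter lens
#' phase (each transposed independently), the JCC phase gated by its
#' activation state, and an optional multifocal contact-lens phase. Piston
#' and tilt terms of the aberrometry are excluded by default since they do
#' not affect image quality (tilt only translates the image).
#'
#' @param eye a [schematic_eye()].
#' @param phoropter a [phoropter_state()] (or NULL).
#' @param jcc a [jcc_state()] (or NULL).
#' @param cl a [multifocal_design()] (or NULL).
#' @param grid a [grid_spec()]; must match the eye's pupil radius.
#' @param include_piston_tilt logical: include OSA terms 0-2 of the eye.
#' @return a `wavefront_map` in micrometres.
#' @export
total_phase <- function(eye, phoropter = NULL, jcc = NULL, cl = NULL,
                        grid = NULL, include_piston_tilt = FALSE) {
  stopifnot(inherits(eye, "schematic_eye"))
  if (is.null(grid)) grid <- grid_spec(eye$pupil_radius,
                                       wavelength = eye$wavelength)
  if (abs(grid$pupil_radius - eye$pupil_radius) > 1e-9)
    stop("grid pupil radius does not match the eye's pupil radius")
  modes <- seq_along(eye$aberrometry$coeffs) - 1L
  if (!include_piston_tilt) modes <- modes[modes >= 3L]
  W <- evaluate_wavefront(eye$aberrometry, grid, include_modes = modes)
  d_v <- if (!is.null(phoropter)) phoropter$vertex_distance * 1e-3 else 0
  if (!is.null(phoropter)) {
    for (sc in phoropter$lenses)
      W <- add_wavefronts(W, lens_phase(sc, d_v, grid, eye$pupil_radius))
  }
  if (!is.null(jcc) && jcc$active)
    W <- add_wavefronts(W, jcc_phase(jcc, d_v, grid, eye$pupil_radius))
  if (!is.null(cl))
    W <- add_wavefronts(W, multifocal_phase(cl, grid, eye$pupil_radius))
  W
}
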