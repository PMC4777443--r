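# Subjective-refraction workflows scripted over the image-formation engine:
# fogging, astigmatic clock dial, JCC axis and power searches with the
# circle-of-least-confusion (CLC) rule, and sphere refinement. The "patient"
# is an automated observer: flip preferences use the Visual Strehl ratio of
# the two rendered states, flip equality uses the rendered image-pair
# similarity, and acuity judgements use the template-correlation estimator.

#' Refraction session: scene plus trial correction and history
#'
#' @param eye a [schematic_eye()] or a raw [zernike_coefficients()] object.
#' @param pupil_radius simulation pupil radius in mm (defaults to the eye's).
#' @param vertex_distance phoropter vertex distance in mm (default 0: trial
#'   corrections expressed at the corneal/pupil plane, as for a contact-lens
#'   plane refraction).
#' @param cl optional [multifocal_design()] worn during the session.
#' @param n_pupil,pad_factor sampling controls forwarded to [grid_spec()]
#'   (session default 128 / 2: coarse enough for interactive-speed
#'   procedures, fine enough for the 0.25 D / 5 degree decision quanta).
#' @param tau_eq image-pair similarity threshold declaring two flip images
#'   equal (default 0.995).
#' @param dial_cv_threshold coefficient-of-variation threshold under which
#'   the 12 dial lines count as equally sharp (default 0.03).
#' @return An object of class `refraction_session`.
#' @export
refraction_session <- function(eye, pupil_radius = NULL, vertex_distance = 0,
                               cl = NULL, n_pupil = 128, pad_factor = 2,
                               tau_eq = 0.995, dial_cv_threshold = 0.03) {
  if (inherits(eye, "zernike_coefficients"))
    eye <- schematic_eye(eye, pupil_radius)
  stopifnot(inherits(eye, "schematic_eye"))
  if (!is.null(pupil_radius) &&
      abs(pupil_radius - eye$pupil_radius) > 1e-9)
    eye <- schematic_eye(eye$aberrometry, pupil_radius,
                         eye$focal_length, eye$refractive_index,
                         eye$wavelength)
  grid <- grid_spec(eye$pupil_radius, n_pupil = n_pupil,
                    pad_factor = pad_factor, wavelength = eye$wavelength)
  structure(list(
    eye = eye, grid = grid,
    phoropter = phoropter_state(list(sphero_cylinder()), vertex_distance),
    jcc = NULL, cl = cl,
    options = list(tau_eq = tau_eq, dial_cv_threshold = dial_cv_threshold),
    history = list(), results = list()
  ), class = "refraction_session")
}

#' @export
print.refraction_session <- function(x, ...) {
  cat("<refraction_session>\n  trial: ")
  print(session_trial(x))
  cat(sprintf("  pupil radius %.3g mm, vertex %.3g mm, %d history step(s)\n",
              x$eye$pupil_radius, x$phoropter$vertex_distance,
              length(x$history)))
  invisible(x)
}

#' Current trial correction of a session
#' @param session a [refraction_session()].
#' @return a [sphero_cylinder()]: the power-vector sum of the phoropter stack.
#' @export
session_trial <- function(session) phoropter_trial(session$phoropter)

#' Replace the trial correction of a session
#' @param session a [refraction_session()].
#' @param sc the new trial [sphero_cylinder()].
#' @return the updated session.
#' @export
session_set_trial <- function(session, sc) {
  session$phoropter$lenses <- list(as_sphero_cylinder(sc))
  session
}

#' Add a thin lens to the session's trial correction
#' @param session a [refraction_session()].
#' @param sc a [sphero_cylinder()] (or S/C/axis triple) to add.
#' @return the updated session.
#' @export
session_add_lens <- function(session, sc) {
  session_set_trial(session,
                    combine_sphero_cylinders(session_trial(session), sc))
}

log_step <- function(session, procedure, note = "", metrics = list()) {
  session$history[[length(session$history) + 1L]] <- list(
    step = length(session$history) + 1L,
    procedure = procedure, note = note,
    trial = session_trial(session), jcc = session$jcc, metrics = metrics)
  session
}

#' Total wavefront of the session scene
#'
#' @param session a [refraction_session()].
#' @param extra_sphere additional sphere in D applied at the pupil plane
#'   (used by through-focus evaluations).
#' @param jcc a [jcc_state()] overriding the session's (use `NULL` for none).
#' @return a `wavefront_map`.
#' @export
scene_wavefront <- function(session, extra_sphere = 0,
                            jcc = session$jcc) {
  W <- total_phase(session$eye, session$phoropter, jcc, session$cl,
                   session$grid)
  if (extra_sphere != 0) {
    pv <- power_vector(sphero_cylinder(extra_sphere))
    W <- add_wavefronts(W, quadratic_phase(pv[["M"]], 0, 0, session$grid,
                                           session$eye$pupil_radius))
  }
  W
}

#' PSF of the session scene
#' @inheritParams scene_wavefront
#' @return a `psf_image`.
#' @export
scene_psf <- function(session, extra_sphere = 0, jcc = session$jcc) {
  compute_psf(pupil_function(scene_wavefront(session, extra_sphere, jcc)))
}

#' Render a chart through the session scene
#'
#' Applies the anamorphic spectacle magnification of the phoropter stack to
#' the paraxial chart (a no-op at zero vertex distance), then convolves with
#' the scene PSF.
#' @param session a [refraction_session()].
#' @param chart a [chart()]; defaults to a clock dial at the PSF pixel scale.
#' @param jcc optional [jcc_state()] override.
#' @return a `retinal_image`.
#' @export
session_render <- function(session, chart = NULL, jcc = session$jcc) {
  if (is.null(chart))
    chart <- make_clock_dial(pixel_scale = session$grid$pixel_scale)
  if (session$phoropter$vertex_distance > 0)
    chart <- apply_magnification(chart, stack_magnification(session$phoropter))
  render_retinal_image(chart, scene_psf(session, jcc = jcc))
}

#' Fogging: add plus sphere until acuity is degraded to a target
#'
#' Adds plus sphere in +0.25 D steps until the estimated acuity is at or
#' beyond `target_logmar` (default 0.50), pushing both focal lines in front
#' of the retina so the astigmatic dial can be read. Errors if the target is
#' not reached within `max_add` dioptres.
#'
#' @param session a [refraction_session()].
#' @param target_logmar fogged acuity target (default 0.50).
#' @param step sphere increment in D (default 0.25).
#' @param max_add largest total addition allowed in D (default 6).
#' @param initial_add standing fog added unconditionally before the acuity
#'   criterion is checked (default 0). The full pipeline uses +1.00 D: an
#'   acuity already at the target can come from cylinder blur alone while a
#'   focal line still sits behind the retina, and only added plus guarantees
#'   the whole Sturm interval moves in front.
#' @return the updated session (fogging steps logged).
#' @export
fog <- function(session, target_logmar = 0.50, step = 0.25, max_add = 6,
                initial_add = 0) {
  added <- 0
  if (initial_add > 0) {
    session <- session_add_lens(session, sphero_cylinder(initial_add))
    added <- initial_add
    session <- log_step(session, "fog", sprintf("standing +%.2f D", added))
  }
  va <- estimate_va(session, start = target_logmar)
  session <- log_step(session, "fog", "start", list(va = va))
  while (va < target_logmar) {
    if (added + step > max_add + 1e-9)
      stop("fogging target not reached within +", max_add, " D")
    session <- session_add_lens(session, sphero_cylinder(step))
    added <- added + step
    va <- estimate_va(session, start = max(va, target_logmar))
    session <- log_step(session, "fog", sprintf("+%.2f D", added),
                        list(va = va))
  }
  session
}

#' Clock-dial (astigmatic fan) procedure
#'
#' Renders the dial chart, finds the sharpest of the 12 radii, converts its
#' orientation to the minus-cylinder axis (rule of 30: the correcting minus
#' axis lies 90 degrees from the sharpest line's direction), then adds minus
#' cylinder in 0.25 D steps at that axis until the 12 line-sharpness scores
#' are as uniform as possible. If no line stands out at the start the eye is
#' declared free of astigmatism (C = 0).
#'
#' @param session a [refraction_session()]; fog first for reliable results
#'   (a warning is issued if the scene is not fogged).
#' @param max_cylinder most minus cylinder to try, in D (default -4).
#' @param line_width dial spoke width in arcmin (default 5).
#' @return the updated session; the endpoint is stored in
#'   `session$results$clock_dial` as `list(axis, cylinder)` with the axis in
#'   clinical notation (180 for horizontal).
#' @export
clock_dial_procedure <- function(session, max_cylinder = -4, line_width = 5) {
  dial <- make_clock_dial(pixel_scale = session$grid$pixel_scale,
                          line_width = line_width)
  sharp <- dial_line_sharpness(session_render(session, dial))
  session <- log_step(session, "clock_dial", "initial dial",
                      list(cv = sharp$cv, sharpest = sharp$sharpest_deg))
  if (sharp$cv < session$options$dial_cv_threshold) {
    session$results$clock_dial <- list(axis = NA_real_, cylinder = 0)
    return(session)
  }
  axis <- (sharp$sharpest_deg + 90) %% 180
  base <- session_trial(session)
  cyls <- seq(0, max_cylinder, by = -0.25)
  best_cv <- Inf; best_c <- 0
  for (cyl in cyls) {
    trial <- combine_sphero_cylinders(base, sphero_cylinder(0, cyl, axis))
    s <- session_set_trial(session, trial)
    sh <- dial_line_sharpness(session_render(s, dial))
    session <- log_step(s, "clock_dial", sprintf("C %.2f @ %g", cyl, axis),
                        list(cv = sh$cv))
    if (sh$cv < best_cv) { best_cv <- sh$cv; best_c <- cyl }
    else if (sh$cv > 1.5 * best_cv && cyl < best_c) break  # past the minimum
  }
  session <- session_set_trial(
    session, combine_sphero_cylinders(base, sphero_cylinder(0, best_c, axis)))
  session$results$clock_dial <- list(
    axis = if (best_c < 0) clinical_axis(axis) else NA_real_,
    cylinder = best_c)
  session
}

# Render the two flip images of the current JCC on a comparison chart and
# score them: returns VS of each flip and their pairwise similarity.
jcc_flip_pair <- function(session, jcc, chart) {
  a <- jcc; a$flipped <- FALSE
  b <- jcc; b$flipped <- TRUE
  psf_a <- scene_psf(session, jcc = a)
  psf_b <- scene_psf(session, jcc = b)
  img_a <- render_retinal_image(chart, psf_a)
  img_b <- render_retinal_image(chart, psf_b)
  list(vs_a = visual_strehl_psf(psf_a), vs_b = visual_strehl_psf(psf_b),
       similarity = image_pair_similarity(img_a, img_b))
}

default_jcc_chart <- function(session) {
  make_dot_pattern(pixel_scale = session$grid$pixel_scale)
}

#' JCC axis search
#'
#' With the cross cylinder straddling the trial cylinder axis (its plus and
#' minus axes 45 degrees to either side), the two flip images are compared;
#' the trial cylinder axis is rotated toward the minus axis of the preferred
#' flip in coarse then fine steps until the flips are equally blurred
#' (similarity >= `tau_eq`), the rotation direction reverses at the finest
#' step, or the iteration cap is reached.
#'
#' @param session a [refraction_session()] whose trial includes a cylinder.
#' @param jcc_power cross-cylinder power magnitude in D (default 0.50).
#' @param steps rotation step schedule in degrees (default `c(10, 5)`).
#' @param chart comparison chart (default: 50-arcmin dot pattern).
#' @param max_iter iteration cap (default 36).
#' @return the updated session; endpoint in `session$results$jcc_axis`.
#' @export
jcc_axis_search <- function(session, jcc_power = 0.50, steps = c(10, 5),
                            chart = NULL, max_iter = 36) {
  trial <- session_trial(session)
  if (trial$cylinder >= 0)
    stop("JCC axis search needs a cylinder in the trial correction")
  if (is.null(chart)) chart <- default_jcc_chart(session)
  axis <- trial$axis
  step_i <- 1L
  last_dir <- 0
  for (iter in seq_len(max_iter)) {
    jcc <- jcc_state(jcc_power, axis = axis + 45, mode = "axis-search")
    pair <- jcc_flip_pair(session, jcc, chart)
    session <- log_step(session, "jcc_axis",
                        sprintf("axis %g", clinical_axis(axis)),
                        pair[c("vs_a", "vs_b", "similarity")])
    if (pair$similarity >= session$options$tau_eq) break
    # flip A has its minus axis at trial + 45, flip B at trial - 45
    dir <- if (pair$vs_a > pair$vs_b) +1 else if (pair$vs_b > pair$vs_a) -1 else 0
    if (dir == 0) break                      # exact tie: clinical end-point
    if (last_dir != 0 && dir != last_dir) {  # bracketed: refine or stop
      if (step_i >= length(steps)) break
      step_i <- step_i + 1L
    }
    axis <- (axis + dir * steps[step_i]) %% 180
    last_dir <- dir
    session <- session_set_trial(
      session, sphero_cylinder(trial$sphere, trial$cylinder, axis))
  }
  session <- session_set_trial(
    session, sphero_cylinder(trial$sphere, trial$cylinder, axis))
  session$results$jcc_axis <- list(axis = clinical_axis(axis),
                                   iterations = iter)
  session
}

#' JCC power search with the circle-of-least-confusion rule
#'
#' With the cross-cylinder axes aligned with the trial cylinder axis (minus
#' axis parallel, or perpendicular when flipped), the flip images are
#' compared and the trial cylinder is changed in -0.25 D steps toward the
#' preferred flip. When `maintain_clc` is TRUE, every accumulated -0.50 D of
#' cylinder adds +0.25 D of sphere so the spherical equivalent of the trial
#' correction — and hence the position of the circle of least confusion on
#' the retina — is preserved. The search terminates at flip equality or, on
#' oscillation (preferences A, B, A), at the bracketed mid choice.
#'
#' @param session a [refraction_session()] with the cylinder axis settled.
#' @param maintain_clc logical (default TRUE): apply the +0.25 D sphere per
#'   -0.50 D cylinder compensation.
#' @param jcc_power cross-cylinder power magnitude in D (default 0.50).
#' @param chart comparison chart (default: 50-arcmin dot pattern).
#' @param max_iter iteration cap (default 24).
#' @return the updated session; endpoint in `session$results$jcc_power`
#'   (`cylinder`, `bracketed`, `equality`).
#' @export
jcc_power_search <- function(session, maintain_clc = TRUE, jcc_power = 0.50,
                             chart = NULL, max_iter = 24) {
  trial <- session_trial(session)
  if (is.null(chart)) chart <- default_jcc_chart(session)
  axis <- trial$axis
  sphere <- trial$sphere
  cyl <- trial$cylinder
  cyl_accum <- 0            # cylinder added since the search began
  sphere_comp <- 0          # sphere compensation already applied
  dirs <- integer(0)
  bracketed <- FALSE; equality <- FALSE
  apply_state <- function(s, sph, cc) {
    session_set_trial(s, sphero_cylinder(sph, cc, axis))
  }
  for (iter in seq_len(max_iter)) {
    jcc <- jcc_state(jcc_power, axis = axis, mode = "power-search")
    pair <- jcc_flip_pair(session, jcc, chart)
    session <- log_step(session, "jcc_power", sprintf("C %.2f", cyl),
                        pair[c("vs_a", "vs_b", "similarity")])
    if (pair$similarity >= session$options$tau_eq) { equality <- TRUE; break }
    # flip A: JCC minus axis parallel to the trial axis -> prefers more
    # minus cylinder; flip B (perpendicular) -> prefers less
    dir <- if (pair$vs_a > pair$vs_b) -1 else if (pair$vs_b > pair$vs_a) +1 else 0
    if (dir == 0) break
    dirs <- c(dirs, dir)
    n <- length(dirs)
    if (n >= 3 && dirs[n] == dirs[n - 2] && dirs[n] != dirs[n - 1]) {
      # A -> B -> A oscillation: keep the bracketed mid choice
      bracketed <- TRUE
      break
    }
    if (dir == +1 && cyl >= 0) break        # cannot reduce below plano
    cyl <- cyl + dir * 0.25
    cyl_accum <- cyl_accum + dir * 0.25
    if (maintain_clc) {
      target_comp <- 0.25 * floor(-cyl_accum / 0.50 + 1e-9)
      dsph <- target_comp - sphere_comp
      if (dsph != 0) { sphere <- sphere + dsph; sphere_comp <- target_comp }
    }
    session <- apply_state(session, sphere, cyl)
  }
  session <- apply_state(session, sphere, cyl)
  session$results$jcc_power <- list(cylinder = cyl, bracketed = bracketed,
                                    equality = equality, iterations = iter)
  session
}

#' Sphere refinement to "maximum plus for best visual acuity"
#'
#' Scans sphere offsets around the current trial in 0.25 D steps, estimates
#' acuity at each candidate, and keeps the most-plus sphere whose acuity is
#' within one acuity step (0.1 logMAR) of the best found.
#'
#' @param session a [refraction_session()] with the cylinder finalized.
#' @param range half-width of the sphere scan in D (default 1.0).
#' @param step sphere quantum in D (default 0.25).
#' @param va_slack acuity tolerance counted as "equal best" (default 0.1).
#' @return the updated session; endpoint in `session$results$refine_sphere`.
#' @export
refine_sphere <- function(session, range = 1.0, step = 0.25, va_slack = 0.1) {
  trial <- session_trial(session)
  offsets <- seq(range, -range, by = -step)       # most plus first
  vas <- numeric(length(offsets))
  hint <- 0.4
  for (i in seq_along(offsets)) {
    s <- session_set_trial(session, sphero_cylinder(
      trial$sphere + offsets[i], trial$cylinder, trial$axis))
    vas[i] <- estimate_va(s, start = hint)
    hint <- vas[i]
  }
  best <- min(vas)
  keep <- which(vas <= best + va_slack + 1e-9)[1]  # most plus among best
  session <- session_set_trial(session, sphero_cylinder(
    trial$sphere + offsets[keep], trial$cylinder, trial$axis))
  session <- log_step(session, "refine_sphere",
                      sprintf("%+.2f D", offsets[keep]),
                      list(va = vas[keep]))
  session$results$refine_sphere <- list(sphere = trial$sphere + offsets[keep],
                                        va = vas[keep])
  session
}

#' Objective (paraxial) refraction of the current scene
#'
#' Least-squares fits the second-order Zernike terms of the scene's total
#' wavefront over the pupil samples and converts them to the
#' sphero-cylindrical correction still needed to neutralize them — what an
#' autorefractor would report for the eye behind the current trial lenses.
#'
#' @param session a [refraction_session()].
#' @return a [sphero_cylinder()]: the additional correction that would zero
#'   the scene's second-order wavefront.
#' @export
objective_refraction <- function(session) {
  W <- scene_wavefront(session)
  grid <- session$grid
  R <- session$eye$pupil_radius
  xy <- grid_coords(grid)
  r <- sqrt(outer(xy$y^2, xy$x^2, "+"))
  th <- atan2(outer(xy$y, rep(1, length(xy$x))),
              outer(rep(1, length(xy$y)), xy$x))
  m <- W$mask
  rho <- r[m] / R
  Z <- cbind(zernike_poly(3, rho, th[m]), zernike_poly(4, rho, th[m]),
             zernike_poly(5, rho, th[m]))
  cf <- stats::lsfit(Z, W$values[m], intercept = TRUE)$coefficients
  z_res <- zernike_coefficients(c("3" = cf[[2]], "4" = cf[[3]],
                                  "5" = cf[[4]]), R)
  res <- power_vector(zernike_to_sphero_cylinder(z_res))
  power_vector_to_sc(-res[["M"]], -res[["J0"]], -res[["J45"]])
}

round_quarter <- function(x) round(x * 4) / 4

# Objective starting sphere / CLC positioning: add the sphere (0.25 D
# quanta) that zeroes the spherical equivalent of the scene's second-order
# wavefront, placing the circle of least confusion on the retina.
neutralize_spherical_equivalent <- function(session) {
  need <- power_vector(objective_refraction(session))[["M"]]
  add <- round_quarter(need)
  if (add != 0) session <- session_add_lens(session, sphero_cylinder(add))
  log_step(session, "sphere_start", sprintf("%+.2f D (objective)", add))
}

#' Full automated subjective-refraction pipeline
#'
#' Objective starting sphere (autorefractor stand-in: the sphere that zeroes
#' the spherical equivalent of the scene wavefront), fogging to 0.50 logMAR,
#' clock-dial estimation of the cylinder, objective repositioning of the
#' circle of least confusion onto the retina, JCC axis then power refinement,
#' and final sphere adjustment to maximum plus for best acuity.
#'
#' @param session a fresh [refraction_session()].
#' @param maintain_clc forwarded to [jcc_power_search()] (default TRUE).
#' @return the completed session; the final prescription is
#'   `session_trial(session)` and per-stage endpoints sit in
#'   `session$results`.
#' @export
full_refraction <- function(session, maintain_clc = TRUE) {
  session <- neutralize_spherical_equivalent(session)
  session <- fog(session, initial_add = 1.0)
  session <- clock_dial_procedure(session)
  if (session$results$clock_dial$cylinder < 0) {
    session <- neutralize_spherical_equivalent(session)
    session <- jcc_axis_search(session)
    session <- jcc_power_search(session, maintain_clc = maintain_clc)
  } else {
    session <- neutralize_spherical_equivalent(session)
  }
  session <- refine_sphere(session, range = 1.5)
  session$results$final <- session_trial(session)
  session
}
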