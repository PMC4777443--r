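test_that("fogging adds plus sphere until the acuity target is reached", {
  s <- refraction_session(make_eye("emmetrope"), pupil_radius = 3)
  f <- fog(s)
  trial <- session_trial(f)
  expect_gt(trial$sphere, 0)
  expect_gte(estimate_va(f), 0.5)
  # an already-fogged scene gains no further lenses
  f2 <- fog(f)
  expect_equal(session_trial(f2)$sphere, trial$sphere)
})

test_that("the clock dial declares no astigmatism for a spherical eye", {
  s <- refraction_session(make_eye("emmetrope"), pupil_radius = 2)
  s <- session_add_lens(s, sphero_cylinder(1))      # fogged sphere only
  out <- clock_dial_procedure(s)
  expect_equal(out$results$clock_dial$cylinder, 0)
})

test_that("the clock dial endpoint is robust to the spoke width", {
  p1 <- refraction_session(make_eye("P1_like"), pupil_radius = 2)
  p1 <- session_add_lens(p1, sphero_cylinder(1))
  for (w in c(4, 5, 6)) {
    out <- clock_dial_procedure(p1, line_width = w)$results$clock_dial
    expect_equal(out$cylinder, -0.75)
    expect_equal(out$axis, 180)
  }
})

test_that("JCC axis search converges to the true axis from a 20-degree error", {
  p1 <- refraction_session(make_eye("P1_like"), pupil_radius = 2)
  p1 <- session_set_trial(p1, sphero_cylinder(0, -0.75, 160))
  s <- jcc_axis_search(p1)
  expect_lt(axis_diff(s$results$jcc_axis$axis, 180), 5 + 1e-9)
  expect_lte(s$results$jcc_axis$iterations, 36)
  # already-correct axis: no rotation
  ok <- session_set_trial(p1, sphero_cylinder(0, -0.75, 0))
  s2 <- jcc_axis_search(ok)
  expect_lt(axis_diff(s2$results$jcc_axis$axis, 180), 1e-9)
  # a cylinder-free trial is rejected
  expect_error(jcc_axis_search(session_set_trial(p1, sphero_cylinder(0))),
               "cylinder")
})

test_that("JCC power search finds the cylinder and conserves the spherical equivalent", {
  p1 <- refraction_session(make_eye("P1_like"), pupil_radius = 2)
  # start one quantum in, CLC on retina; accumulated change is -0.50 D
  start <- sphero_cylinder(-0.25, -0.25, 0)
  s <- jcc_power_search(session_set_trial(p1, start), maintain_clc = TRUE)
  got <- session_trial(s)
  expect_equal(got$cylinder, -0.75, tolerance = 0.25 + 1e-9)
  expect_identical(power_vector(got)[["M"]], power_vector(start)[["M"]])

  # from C = 0 the accumulated -0.75 D is odd in half-diopter units:
  # the spherical equivalent may lag by at most one half-step (0.125 D)
  start0 <- sphero_cylinder(-0.375, 0, 0)
  s0 <- jcc_power_search(session_set_trial(p1, start0), maintain_clc = TRUE)
  dM <- power_vector(session_trial(s0))[["M"]] - power_vector(start0)[["M"]]
  expect_lte(abs(dM), 0.125 + 1e-12)
  expect_equal(session_trial(s0)$cylinder, -0.75, tolerance = 0.25 + 1e-9)

  # without the CLC rule the spherical equivalent drifts with the cylinder
  su <- jcc_power_search(session_set_trial(p1, start), maintain_clc = FALSE)
  dMu <- power_vector(session_trial(su))[["M"]] - power_vector(start)[["M"]]
  expect_equal(dMu, session_trial(su)$cylinder / 2 - start$cylinder / 2,
               tolerance = 1e-12)
})

test_that("maintaining the CLC yields cleaner equality and a better endpoint", {
  run <- function(clc) {
    p <- refraction_session(make_eye("P1_like"), pupil_radius = 2)
    p <- session_set_trial(p, sphero_cylinder(-0.25, -0.25, 0))
    s <- jcc_power_search(p, maintain_clc = clc)
    sims <- vapply(s$history, function(h)
      if (!is.null(h$metrics$similarity)) h$metrics$similarity else NA_real_,
      numeric(1))
    list(sim = utils::tail(stats::na.omit(sims), 1),
         vs = visual_strehl(scene_wavefront(s)))
  }
  a <- run(TRUE); b <- run(FALSE)
  expect_gt(a$sim, b$sim)
  expect_gte(a$vs, b$vs)
})

test_that("sphere refinement stops at maximum plus for best acuity", {
  # overminused spherical eye: refinement walks back to plano
  s <- refraction_session(make_eye("emmetrope"), pupil_radius = 3)
  s <- session_set_trial(s, sphero_cylinder(-0.5))
  r <- refine_sphere(s)
  expect_equal(session_trial(r)$sphere, 0, tolerance = 0.25 + 1e-9)
  # an already-optimal trial is unchanged
  s2 <- refine_sphere(session_set_trial(s, sphero_cylinder(0)))
  expect_equal(session_trial(s2)$sphere, 0, tolerance = 0.25 + 1e-9)
})

test_that("session history is append-only and regenerates its images", {
  p1 <- refraction_session(make_eye("P1_like"), pupil_radius = 2)
  p1 <- session_add_lens(p1, sphero_cylinder(1))
  out <- clock_dial_procedure(p1)
  expect_gt(length(out$history), 1)
  steps <- vapply(out$history, function(h) h$step, integer(1))
  expect_equal(steps, seq_along(steps))
  # re-rendering the scene of a logged step is bit-identical
  h <- out$history[[2]]
  s_replay <- session_set_trial(p1, h$trial)
  img1 <- session_render(s_replay)
  img2 <- session_render(s_replay)
  expect_identical(img1$image, img2$image)
})

test_that("session rendering applies the stack's spectacle magnification", {
  s0 <- refraction_session(make_eye("emmetrope"), pupil_radius = 2,
                           vertex_distance = 15)
  s5 <- session_set_trial(s0, sphero_cylinder(5))
  ch <- make_dot_pattern(pixel_scale = s0$grid$pixel_scale)
  auto <- session_render(s5, ch)
  manual <- render_retinal_image(
    apply_magnification(ch, stack_magnification(s5$phoropter)),
    scene_psf(s5))
  expect_identical(auto$image, manual$image)
  # the magnification really is the 1.081 of a +5 D lens at 15 mm
  sm <- stack_magnification(s5$phoropter)
  expect_equal(sm$sm_axis, 1 / (1 - 0.015 * 5), tolerance = 1e-12)
  # and at zero vertex distance rendering is untouched
  z0 <- refraction_session(make_eye("emmetrope"), pupil_radius = 2)
  z5 <- session_set_trial(z0, sphero_cylinder(5))
  expect_identical(session_render(z5, ch)$image,
                   render_retinal_image(ch, scene_psf(z5))$image)
})

test_that("the objective refraction reports the residual correction", {
  z <- make_eye("random_loa", seed = 11, pupil_radius = 3)
  truth <- attr(z, "refraction")
  s <- refraction_session(z, pupil_radius = 2)
  need <- objective_refraction(s)
  expect_equal(need$sphere, truth$sphere, tolerance = 0.05)
  expect_equal(need$cylinder, truth$cylinder, tolerance = 0.05)
  if (truth$cylinder < -0.1)
    expect_lt(axis_diff(need$axis, truth$axis), 2)
})
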