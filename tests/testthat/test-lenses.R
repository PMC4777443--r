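test_that("vertex power transposition and spectacle magnification match closed forms", {
  expect_equal(effective_power_at_pupil(0, 0.015), 0)
  expect_equal(effective_power_at_pupil(5, 0.015), 5 / (1 - 0.075),
               tolerance = 1e-12)
  expect_equal(effective_power_at_pupil(-5, 0.015), -5 / 1.075,
               tolerance = 1e-12)
  expect_equal(spectacle_magnification(0, 0.015), 1)
  expect_equal(spectacle_magnification(5, 0.015), 1 / 0.925,
               tolerance = 1e-12)
  expect_equal(spectacle_magnification(-5, 0.015), 1 / 1.075,
               tolerance = 1e-12)
  # d_v = 0 identities for arbitrary powers
  for (F in c(-8, -1.25, 3.5, 10))
    expect_equal(c(effective_power_at_pupil(F, 0),
                   spectacle_magnification(F, 0)), c(F, 1))
  expect_error(effective_power_at_pupil(10, 0.1), "focal point")

  # anamorphic form for a sphero-cylinder
  sm <- spectacle_magnification(sphero_cylinder(2, -1, 30), 0.015)
  expect_equal(sm$sm_axis, 1 / (1 - 0.015 * 2), tolerance = 1e-12)
  expect_equal(sm$sm_perp, 1 / (1 - 0.015 * 1), tolerance = 1e-12)
  expect_equal(sm$meridian_deg, 30)
})

test_that("lens phase matches the second-order Zernike map of the same power", {
  g <- grid_spec(3, n_pupil = 64)
  # plano lens contributes nothing
  expect_true(all(lens_phase(sphero_cylinder(), 0, g)$values == 0))
  # +1.00 DS at d_v = 0 equals the wavefront of its Zernike conversion up to
  # piston (the orthonormal defocus polynomial carries a constant offset)
  W1 <- lens_phase(sphero_cylinder(1), 0, g)
  W2 <- evaluate_wavefront(sphero_cylinder_to_zernike(sphero_cylinder(1), 3), g)
  d1 <- W1$values[W1$mask] - mean(W1$values[W1$mask])
  d2 <- W2$values[W2$mask] - mean(W2$values[W2$mask])
  expect_lt(max(abs(d1 - d2)), 1e-9)
  # cylinder meridional sag: -1.00 x 90 puts all its power in the horizontal
  # meridian: W(x, 0) = +x^2/2, W(0, y) = 0
  Wc <- lens_phase(sphero_cylinder(0, -1, 90), 0, g)
  xy <- refractsim:::grid_coords(g)
  c0 <- g$n_pupil %/% 2 + 1
  expect_equal(Wc$values[c0, ], ifelse(Wc$mask[c0, ], 0.5 * xy$x^2, 0),
               tolerance = 1e-12)
  expect_equal(Wc$values[, c0], rep(0, g$n_pupil), tolerance = 1e-12)
})

test_that("JCC algebra: zero spherical equivalent, flip involution, exact negation", {
  j <- jcc_state(0.50, axis = 35)
  sc <- jcc_equivalent_sc(j)
  pv <- power_vector(sc)
  expect_equal(pv[["M"]], 0)
  expect_equal(sqrt(pv[["J0"]]^2 + pv[["J45"]]^2), 0.50, tolerance = 1e-12)

  # flip negates (J0, J45) exactly, for any axis
  for (ax in c(0, 35, 90, 122.5)) {
    ja <- jcc_state(0.5, axis = ax)
    pa <- power_vector(jcc_equivalent_sc(ja))
    pb <- power_vector(jcc_equivalent_sc(jcc_flip(ja)))
    expect_equal(pb[["J0"]], -pa[["J0"]], tolerance = 1e-12)
    expect_equal(pb[["J45"]], -pa[["J45"]], tolerance = 1e-12)
  }

  # two flips restore the phase map bit-exactly
  g <- grid_spec(3, n_pupil = 64)
  W0 <- jcc_phase(j, 0.012, g)
  W2 <- jcc_phase(jcc_flip(jcc_flip(j)), 0.012, g)
  expect_identical(W0$values, W2$values)

  # inactive JCC contributes the zero map
  joff <- jcc_state(0.5, active = FALSE)
  expect_true(all(jcc_phase(joff, 0.012, g)$values == 0))
})

test_that("multifocal phase is the piecewise defocus of each annulus", {
  g <- grid_spec(3, n_pupil = 128)
  # single plano zone
  flat <- multifocal_phase(multifocal_design(data.frame(r = 3, add = 0)), g)
  expect_true(all(flat$values == 0))
  # CL1: check W = -add * r^2 / 2 inside each annulus at sample radii
  W <- multifocal_phase(cl1_design(), g)
  xy <- refractsim:::grid_coords(g)
  c0 <- g$n_pupil %/% 2 + 1
  probe <- function(r_mm) {
    i <- which.min(abs(xy$x - r_mm))
    c(W$values[c0, i], xy$x[i])
  }
  p1 <- probe(0.8);  expect_equal(p1[1], -0.5 * 2 * p1[2]^2, tolerance = 1e-9)
  p2 <- probe(2.0);  expect_equal(p2[1], -0.5 * 1 * p2[2]^2, tolerance = 1e-9)
  p3 <- probe(2.7);  expect_equal(p3[1], 0, tolerance = 1e-9)
  # CL2 has exactly two distinct curvatures (near add and plano)
  W2 <- multifocal_phase(cl2_design(), g)
  r2 <- outer(xy$y^2, xy$x^2, "+")
  curv <- round(-2 * W2$values[W2$mask & r2 > 1e-6] / r2[W2$mask & r2 > 1e-6], 6)
  expect_setequal(unique(curv), c(0, 2))
  # a design not covering the pupil is rejected
  expect_error(
    multifocal_phase(multifocal_design(data.frame(r = 2, add = 1)), g),
    "cover")
})

test_that("total phase is the additive composition of its contributors", {
  z <- make_eye("P2_like", seed = 3)
  eye <- schematic_eye(z, pupil_radius = 2.5)
  g <- grid_spec(2.5, n_pupil = 64)
  ph <- phoropter_state(list(sphero_cylinder(-1, -0.5, 20)), vertex_distance = 12)
  j <- jcc_state(0.5, axis = 65)
  cl <- cl1_design()
  W_all <- total_phase(eye, ph, j, cl, g)
  W_sum <- evaluate_wavefront(eye$aberrometry, g,
                              include_modes = 3:(length(eye$aberrometry$coeffs) - 1))$values +
    lens_phase(sphero_cylinder(-1, -0.5, 20), 0.012, g)$values +
    jcc_phase(j, 0.012, g)$values +
    multifocal_phase(cl, g)$values
  expect_lt(max(abs(W_all$values - W_sum)), 1e-10)

  # eye-only scene reproduces the aberrometry map (above piston/tilt)
  W_eye <- total_phase(eye, grid = g)
  W_ref <- evaluate_wavefront(eye$aberrometry, g,
                              include_modes = 3:(length(eye$aberrometry$coeffs) - 1))
  expect_lt(max(abs(W_eye$values - W_ref$values)), 1e-12)

  # eye + its exact correcting lens at d_v = 0 leaves no second-order power
  p1 <- make_eye("P1_like")
  eye1 <- schematic_eye(p1, pupil_radius = 3)
  corr <- phoropter_state(list(sphero_cylinder(0, -0.75, 180)),
                          vertex_distance = 0)
  s <- refraction_session(p1, pupil_radius = 3)
  s$phoropter <- corr
  resid <- objective_refraction(s)
  expect_equal(resid$sphere, 0, tolerance = 1e-6)
  expect_equal(resid$cylinder, 0, tolerance = 1e-6)
})

test_that("schematic eye rescales aberrometry and validates the pupil", {
  z <- make_eye("P2_like", seed = 1)           # measured at 3 mm
  eye <- schematic_eye(z, pupil_radius = 2)
  expect_equal(eye$aberrometry$pupil_radius, 2)
  expect_error(schematic_eye(z, pupil_radius = 4), "exceeds")
  expect_equal(eye$focal_length, 22.4)
  expect_equal(eye$refractive_index, 1.33)
  expect_equal(eye$wavelength, 587)
})
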