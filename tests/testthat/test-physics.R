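test_that("wavenumbers follow the closed forms and the decaying branch", {
  cfg <- optical_config()
  wn <- derive_wavenumbers(cfg)
  expect_equal(wn$k0, 2 * pi / 633, tolerance = 1e-12)
  expect_equal(wn$k_d, cfg$dielectric_index * wn$k0, tolerance = 1e-12)
  # independent complex-arithmetic evaluation of k_sp/k0 = sqrt(em/(em+1))
  em <- cfg$metal_permittivity
  ratio <- sqrt(em / (em + 1))
  if (Im(ratio) > 0) ratio <- Conj(ratio)
  expect_equal(wn$k_sp / wn$k0, ratio, tolerance = 1e-12)
  expect_gte(wn$k_dprime, 0)
  expect_lte(Im(wn$k_sp), 0)

  # asymptotic limit: a nearly perfect conductor carries k_sp -> n k0
  wn2 <- derive_wavenumbers(optical_config(metal_permittivity = -1e10 + 0i))
  expect_equal(Re(wn2$k_sp) / wn2$k_d, 1, tolerance = 1e-6)
  expect_lt(wn2$k_dprime / wn2$k0, 1e-8)
})

test_that("configurations without a bound surface plasmon are rejected", {
  expect_error(optical_config(metal_permittivity = -0.5 + 0.1i),
               "surface plasmon")
  expect_error(optical_config(metal_permittivity = -1.2 + 0i,
                              dielectric_index = 1.33),
               "surface plasmon")
})

test_that("reference wave is a unit-modulus plane wave with the stated phase", {
  cfg <- optical_config(incident_angle = 0.7, phase_offset = 0,
                        film_thickness = 0, propagation_angle = 0)
  er <- reflected_field(cfg, 16, 16)
  expect_equal(er[1, 1], 1 + 0i, tolerance = 1e-12)      # physical origin
  expect_lt(max(abs(Mod(er) - 1)), 1e-12)                # unit modulus

  # phase at (x = delta, y = 0): -k_d * delta * sin(theta) + phase_offset
  cfg2 <- optical_config(incident_angle = 0.7, phase_offset = 0.3,
                         film_thickness = 0, propagation_angle = 0)
  wn <- derive_wavenumbers(cfg2)
  er2 <- reflected_field(cfg2, 4, 8)
  delta <- 5 * cfg2$pixel_size
  expected <- (-wn$k_d * delta * sin(0.7) + 0.3) %% (2 * pi)
  expect_equal(Arg(er2[1, 6]) %% (2 * pi), expected, tolerance = 1e-9)
})

test_that("object wave decays and oscillates at the SP propagation constant", {
  cfg <- oracle_config()
  wn <- derive_wavenumbers(cfg)
  sc <- scatterers(10, 12, amplitude = 0.05, phase = 0)
  eo <- object_field(cfg, sc, 32, 32)

  # value at the scatterer equals alpha * E_R(r') * exp(kappa_z z)
  er <- reflected_field(cfg, 32, 32)
  expect_equal(eo[13, 11],
               0.05 * er[13, 11] * exp(wn$kappa_z * cfg$bfp_offset),
               tolerance = 1e-12)

  # radial decay law along a row through the scatterer
  d1 <- 4 * cfg$pixel_size
  d2 <- 9 * cfg$pixel_size
  ratio <- Mod(eo[13, 11 + 9]) / Mod(eo[13, 11 + 4])
  expect_equal(ratio, exp(-2 * wn$k_dprime * (d2 - d1)), tolerance = 1e-10)

  # phase advance between radii is -k_prime * delta (mod 2 pi)
  dphi <- (Arg(eo[13, 11 + 9]) - Arg(eo[13, 11 + 4])) %% (2 * pi)
  expect_equal(dphi, (-wn$k_prime * (d2 - d1)) %% (2 * pi), tolerance = 1e-8)

  # log-magnitude along a ray is affine in distance with slope -2 k''
  dists <- (1:15) * cfg$pixel_size
  mags <- Mod(eo[13, 11 + 1:15])
  fit <- stats::lm(log(mags) ~ dists)
  expect_equal(unname(stats::coef(fit)[2]), -2 * wn$k_dprime,
               tolerance = 1e-6)

  expect_error(object_field(cfg, scatterers(40, 2, 0.05, 0), 32, 32),
               "outside")
})

test_that("intensity modes satisfy their algebraic identities", {
  cfg <- oracle_config()
  er <- reflected_field(cfg, 24, 24)
  eo <- object_field(cfg, scatterers(11, 13, 0.08, 0.5), 24, 24)

  zero <- eo * 0
  expect_true(all(ipm_intensity(er, zero, "full") == 0))
  expect_true(all(ipm_intensity(er, zero, "linearized") == 0))

  full <- ipm_intensity(er, eo, "full")
  lin <- ipm_intensity(er, eo, "linearized")
  expect_equal(unclass(full - lin), unclass(Mod(eo)^2), tolerance = 1e-12)

  # linearized is linear in the object wave; full is not
  lin2 <- ipm_intensity(er, 2 * eo, "linearized")
  expect_equal(unclass(lin2), unclass(2 * lin), tolerance = 1e-12)
  full2 <- ipm_intensity(er, 2 * eo, "full")
  expect_gt(max(abs(full2 - 2 * full)), 0)

  expect_error(ipm_intensity(er, eo[1:10, 1:10], "full"), "dimensions")
})

test_that("render_scene composes, superposes, and is antisymmetric in phase", {
  cfg <- oracle_config()
  expect_true(all(render_scene(cfg, scatterers(), 16, 16) == 0))

  sc1 <- scatterers(5, 6, 0.04, 0.3)
  one <- render_scene(cfg, sc1, 16, 16, "full")
  er <- reflected_field(cfg, 16, 16)
  eo <- object_field(cfg, sc1, 16, 16)
  expect_equal(unclass(one), unclass(ipm_intensity(er, eo, "full")),
               tolerance = 1e-14)

  # two-scatterer superposition in linearized mode, pixelwise
  sc2 <- scatterers(11, 9, 0.06, -1.2)
  both <- render_scene(cfg, dplyr::bind_rows(sc1, sc2), 16, 16, "linearized")
  expect_equal(
    unclass(both),
    unclass(render_scene(cfg, sc1, 16, 16, "linearized") +
              render_scene(cfg, sc2, 16, 16, "linearized")),
    tolerance = 1e-14
  )

  # flipping the scatterer phase by pi negates the linearized image exactly
  flipped <- scatterers(sc1$x, sc1$y, sc1$amplitude, sc1$phase + pi)
  expect_equal(
    unclass(render_scene(cfg, flipped, 16, 16, "linearized")),
    unclass(-render_scene(cfg, sc1, 16, 16, "linearized")),
    tolerance = 1e-12
  )
})

test_that("linearization error is bounded by the object-wave energy", {
  cfg <- oracle_config()
  for (alpha in c(0.1, 0.01, 0.001)) {
    sc <- scatterers(8, 8, alpha, 0.7)
    full <- render_scene(cfg, sc, 16, 16, "full")
    lin <- render_scene(cfg, sc, 16, 16, "linearized")
    expect_lte(max(abs(full - lin)), alpha^2 + 1e-15)
  }
})

test_that("renderer matches the scalar brute-force oracle on a 16x16 grid", {
  cfg <- oracle_config()
  scene <- scatterers(c(4.3, 11.7), c(5.1, 9.2), c(0.05, 0.08), c(0.4, -2.1))
  for (mode in c("full", "linearized")) {
    got <- render_scene(cfg, scene, 16, 16, mode)
    want <- bf_render(cfg, scene, 16, 16, mode)
    expect_lt(max(abs(got - want)) / max(abs(want)), 1e-10)
  }
})
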