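test_that("radius of gyration: symmetry, solid-sphere limit, invariance", {
  # two equal masses 20 A apart -> Rg = 10 A = 1 nm
  expect_equal(radius_of_gyration(toy_structures("two_point", d = 20)), 1)

  # dense uniform solid sphere -> sqrt(3/5) R
  sb <- toy_structures("bead_sphere", radius = 20, n_beads = 10000, seed = 1)
  expect_equal(radius_of_gyration(sb), sqrt(3 / 5) * 2, tolerance = 0.01)
  expect_equal(radius_of_gyration(sb), attr(sb, "truth")$rg_nm, tolerance = 0.01)

  # rigid rotation + translation leaves Rg unchanged
  set.seed(5)
  R <- rand_rotation()
  xyz <- as.matrix(sb[, c("x", "y", "z")]) %*% t(R)
  moved <- structure_model(data.frame(element = sb$element,
                                      x = xyz[, 1] + 13, y = xyz[, 2] - 7,
                                      z = xyz[, 3] + 2),
                           mass = sb$mass)
  expect_equal(radius_of_gyration(moved), radius_of_gyration(sb),
               tolerance = 1e-9)

  # mass vs uniform weighting differ when masses differ
  s <- structure_model(data.frame(element = c("C", "O"), x = c(0, 10),
                                  y = 0, z = 0))
  expect_false(radius_of_gyration(s, "mass") == radius_of_gyration(s, "uniform"))
  expect_warning(rg1 <- radius_of_gyration(
    structure_model(data.frame(element = "C", x = 0, y = 0, z = 0))))
  expect_equal(rg1, 0)
})

test_that("solvent-accessible surface: closed forms, split, convergence", {
  iso <- 4 * pi * (1.9 + 1.4)^2  # isolated sphere, r = 1.9 A, probe 1.4 A

  one <- structure_model(data.frame(element = "C", x = 0, y = 0, z = 0),
                         radius = 1.9)
  expect_equal(sasa(one)$total * 100, iso, tolerance = 1e-10)

  # additivity at large separation
  far <- toy_structures("dumbbell", d = 100, atom_radius = 1.9)
  expect_equal(sasa(far)$total * 100, 2 * iso, tolerance = 1e-10)

  # coincident duplicate contributes zero marginal area
  dup <- structure_model(data.frame(element = c("C", "C"), x = 0, y = 0, z = 0),
                         radius = 1.9)
  expect_equal(sasa(dup)$total * 100, iso, tolerance = 1e-10)

  # two overlapping spheres against a Monte-Carlo rejection oracle
  centers <- rbind(c(0, 0, 0), c(3.0, 0, 0))
  overl <- structure_model(data.frame(element = c("C", "N"),
                                      x = centers[, 1], y = centers[, 2],
                                      z = centers[, 3]),
                           radius = 1.9)
  got <- sasa(overl)
  oracle <- mc_sasa(centers, c(1.9, 1.9), n = 60000, seed = 3)
  expect_equal(got$total * 100, oracle, tolerance = 0.02)

  # polarity split is exact and respects element classes (C,S vs N,O,P)
  expect_equal(got$hydrophobic + got$hydrophilic, got$total, tolerance = 1e-12)
  expect_gt(got$hydrophobic, 0)
  expect_gt(got$hydrophilic, 0)

  # doubling the sphere-point count moves totals by < 0.5%
  sb <- toy_structures("bead_sphere", radius = 8, n_beads = 60, seed = 2)
  a1 <- sasa(sb, n_sphere_points = 960)$total
  a2 <- sasa(sb, n_sphere_points = 1920)$total
  expect_lt(abs(a2 - a1) / a1, 0.005)

  expect_error(sasa(one, probe_radius = 0), class = "protomer_domain_error")
  expect_error(sasa(one, n_sphere_points = 50), class = "protomer_domain_error")
})

test_that("Stokes-Einstein conversions", {
  # closed-form arithmetic check at 37 C in water
  expect_equal(stokes_einstein_diameter(1.218e-10, 310.15, 6.913e-4), 5.4,
               tolerance = 1e-3)
  # inverse pair is the identity
  d0 <- 5.4
  expect_equal(stokes_einstein_diameter(stokes_einstein_diffusion(d0)), d0,
               tolerance = 1e-12)
  # doubling viscosity halves the diffusion coefficient at fixed diameter
  expect_equal(stokes_einstein_diffusion(d0, viscosity = 2 * 6.913e-4),
               stokes_einstein_diffusion(d0) / 2, tolerance = 1e-12)
  expect_error(stokes_einstein_diameter(-1), class = "protomer_domain_error")
})

test_that("DLS cumulant analysis recovers diffusion from a correlogram", {
  q <- scattering_vector()
  tau <- 10^seq(-6.5, -3.5, length.out = 150)

  # monodisperse: exact recovery, vanishing polydispersity
  D <- stokes_einstein_diffusion(5.4)
  r <- dls_cumulant_diameter(tau, 0.85 * exp(-2 * D * q^2 * tau))
  expect_equal(r$diffusion, D, tolerance = 1e-3)
  expect_equal(r$diameter_nm, 5.4, tolerance = 1e-3)
  expect_lt(r$pdi, 0.01)

  # full pipeline composed on synthetic data returns the generating diameter
  expect_equal(r$diameter_nm, 5.4, tolerance = 0.005)

  # 50/50 bimodal: mean decay rate falls between the two pure rates
  G1 <- stokes_einstein_diffusion(4) * q^2
  G2 <- stokes_einstein_diffusion(8) * q^2
  g1 <- 0.5 * exp(-G1 * tau) + 0.5 * exp(-G2 * tau)
  rb <- dls_cumulant_diameter(tau, g1^2)
  expect_gt(rb$gamma, G2)
  expect_lt(rb$gamma, G1)
  expect_gt(rb$pdi, 0.01)

  # flat correlogram has no decay to fit
  expect_error(dls_cumulant_diameter(tau, rep(0.9, length(tau))),
               class = "protomer_fit_failure")
  expect_error(dls_cumulant_diameter(tau[1:5], rep(1, 5)),
               class = "protomer_domain_error")
})

test_that("SEC calibration line and apparent molecular weight", {
  # standards exactly on a line: R^2 = 1 and exact interpolation
  V <- c(9, 11, 13, 15, 17)
  mw <- 10^(5 - 0.2 * V)
  cal <- sec_calibrate(mw, V)
  expect_equal(cal$r_squared, 1, tolerance = 1e-12)
  expect_equal(cal$slope, -0.2, tolerance = 1e-10)
  for (i in seq_along(V))
    expect_equal(mw_from_elution(cal, V[i]), mw[i], tolerance = 1e-9)

  # midpoint of two standards -> geometric mean of their MWs
  expect_equal(mw_from_elution(cal, (V[1] + V[2]) / 2), sqrt(mw[1] * mw[2]),
               tolerance = 1e-9)

  # prediction strictly decreasing in elution volume for negative slope
  vv <- seq(9, 17, 0.5)
  expect_true(all(diff(mw_from_elution(cal, vv)) < 0))

  # noisy standards: slope recovered within 2 standard errors
  set.seed(8)
  logmw <- 5 - 0.2 * V + rnorm(length(V), 0, 0.03)
  caln <- sec_calibrate(10^logmw, V)
  se <- summary(lm(logmw ~ V))$coefficients["V", "Std. Error"]
  expect_lt(abs(caln$slope - (-0.2)), 2 * se + 1e-12)

  # extrapolation is flagged
  expect_warning(mw_from_elution(cal, 25), "extrapolat")
  expect_error(sec_calibrate(mw[1:2], V[1:2]),
               class = "protomer_insufficient_data")
  expect_error(sec_calibrate(mw, rep(10, 5)), class = "protomer_domain_error")
})
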