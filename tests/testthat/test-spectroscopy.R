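test_that("stick spectrum converts energies and keeps dark states at zero weight", {
  dye <- build_dye_only(12500, 3)
  sk <- stick_spectrum(diagonalize(build_hamiltonian(dye)))
  expect_equal(sk$wavelength_nm, 800)
  expect_equal(sk$dipole_strength_D2, 9)

  # H-aggregate dimer: two states, exactly one carries weight
  E <- 12800; V <- 35
  basis <- data.frame(site = 0:1, role = "ring", label = "ring-axial",
                      x = c(0, 1), y = 0, z = 0, dx = 0, dy = 0, dz = 1,
                      mu_D = 2, E_cm1 = E, stringsAsFactors = FALSE)
  st <- diagonalize(exciton_hamiltonian(matrix(c(E, V, V, E), 2, 2), basis))
  sk2 <- stick_spectrum(st)
  expect_equal(nrow(sk2), 2L)
  expect_equal(sum(sk2$dipole_strength_D2 > 0), 1L)
  # total stick weight obeys the sum rule
  expect_equal(sum(sk2$dipole_strength_D2), 8, tolerance = 1e-6)
})

test_that("broadening conserves integrated intensity and is linear", {
  lp <- lineshape_params("gaussian", 350, c(580, 1150), 0.1)
  one <- data.frame(wavelength_nm = 800, dipole_strength_D2 = 2)
  sp <- broaden(one, lp)
  E <- nm_to_cm1(sp$wavelength_nm)
  o <- order(E)
  integ <- sum(diff(E[o]) * (head(sp$absorbance[o], -1) +
                               tail(sp$absorbance[o], -1)) / 2)
  expect_equal(integ, 2 * nm_to_cm1(800), tolerance = 1e-3)

  two <- data.frame(wavelength_nm = c(800, 800),
                    dipole_strength_D2 = c(2, 2))
  expect_equal(broaden(two, lp)$absorbance, 2 * sp$absorbance,
               tolerance = 1e-12)

  # narrow-linewidth limit: peak at the stick position within one grid step
  lpn <- lineshape_params("gaussian", 5, c(700, 900), 0.1)
  spn <- broaden(one, lpn)
  expect_lt(abs(spn$wavelength_nm[which.max(spn$absorbance)] - 800), 0.1)

  # lorentzian kernel is accepted too
  spl <- broaden(one, lineshape_params("lorentzian", 350, c(700, 900), 0.25))
  expect_true(all(spl$absorbance >= 0))

  # a grid excluding all sticks warns
  expect_warning(broaden(one, lineshape_params("gaussian", 350, c(400, 500),
                                               0.25)),
                 "empty spectrum")
})

test_that("single-band calibration recovers the closed-form site energy", {
  dye <- build_dye_only(13000, 5)
  cal <- calibrate_ring(dye, data.frame(wavelength_nm = 790),
                        free = "dye_energy", lp = lineshape_params())
  expect_equal(unname(cal$par), 1e7 / 790, tolerance = 1e-6)
  expect_lt(cal$residual, 1e-4)
})

test_that("calibration is a fixed point on already-calibrated parameters", {
  m <- default_model()
  cal1 <- m$calibration
  targets <- data.frame(wavelength_nm = c(810, 760),
                        rel_intensity = c(1, 0.55))
  free <- c("site_energy_tangential", "site_energy_axial", "mu_tangential")
  cal2 <- calibrate_ring(cal1$geometry, targets, free = free,
                         lp = m$lineshape,
                         screening_n = m$config$environment$screening_n)
  expect_lt(max(abs(cal2$par - cal1$par) / abs(cal1$par)), 1e-6)
  expect_lt(cal1$residual, 1e-3)
})

test_that("three-band targets still pin the lowest-energy maximum at 810 nm", {
  cfg <- default_config()
  ring <- build_ring(6, 1.2, cfg$energies$site_energy_tangential_cm1,
                     cfg$energies$site_energy_axial_cm1,
                     cfg$dipoles$mu_tangential_D, cfg$dipoles$mu_axial_D)
  cal <- calibrate_ring(ring, data.frame(wavelength_nm = c(810, 760, 715)),
                        free = c("site_energy_tangential",
                                 "site_energy_axial"),
                        lp = lineshape_params())
  expect_lt(abs(max(cal$fitted_peaks$wavelength_nm) - 810), 2)
})

test_that("spectral additivity is exact at zero coupling and worsens with coupling", {
  m <- default_model()
  lp <- m$lineshape
  sn <- m$config$environment$screening_n
  spec_of <- function(scale) {
    st <- diagonalize(build_hamiltonian(m$geometry$A, screening_n = sn,
                                        dye_coupling_scale = scale))
    broaden(stick_spectrum(st), lp)
  }
  ring_sp <- m$spectra$ring
  dye_sp <- m$spectra$dye
  expect_lt(additivity_residual(spec_of(0), ring_sp, dye_sp), 1e-10)
  r1 <- additivity_residual(spec_of(1), ring_sp, dye_sp)
  r2 <- additivity_residual(spec_of(2), ring_sp, dye_sp)
  expect_lt(r1, 0.05)   # too subtle to detect experimentally
  expect_gt(r1, 0)
  expect_gte(r2, r1)    # doubling the coupling does not improve additivity
  # mismatched grids are rejected
  other <- broaden(stick_spectrum(m$states$dye),
                   lineshape_params("gaussian", 350, c(600, 901), 0.25))
  expect_error(additivity_residual(spec_of(1), ring_sp, other),
               "grid mismatch")
})

test_that("dipole redistribution is zero without coupling, positive towards the dye, and second order", {
  m <- default_model()
  sn <- m$config$environment$screening_n
  st0 <- diagonalize(build_hamiltonian(m$geometry$A, screening_n = sn,
                                       dye_coupling_scale = 0))
  expect_identical(dipole_redistribution(st0, st0), 0)
  st1 <- diagonalize(build_hamiltonian(m$geometry$A, screening_n = sn))
  expect_gt(dipole_redistribution(st1, st0), 0)

  # (V / Delta)^2 scaling on a two-level reduction with orthogonal dipoles
  gain <- function(V) {
    dipole_redistribution(diagonalize(toy_two_level(V)),
                          diagonalize(toy_two_level(0)), dye_index = 1)
  }
  expect_equal(gain(20) / gain(10), 4, tolerance = 0.02)
  expect_equal(gain(10) / gain(5), 4, tolerance = 0.01)
})
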