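test_that("point-dipole coupling reproduces the orientation-factor identities", {
  td <- function(o, d) transition_dipole(o, d, 1, 13000)
  # parallel dipoles perpendicular to R: kappa = 1; frozen SI evaluation
  side <- dipole_coupling(td(c(0, 0, 0), c(0, 0, 1)),
                          td(c(1, 0, 0), c(0, 0, 1)), screening_n = 1)
  expect_equal(side, 5.0341, tolerance = 1e-4)
  # collinear head-to-tail: kappa = -2
  coll <- dipole_coupling(td(c(0, 0, 0), c(1, 0, 0)),
                          td(c(1, 0, 0), c(1, 0, 0)), screening_n = 1)
  expect_equal(coll / side, -2, tolerance = 1e-12)
  # screening scales as 1/n^2
  expect_equal(dipole_coupling(td(c(0, 0, 0), c(0, 0, 1)),
                               td(c(1, 0, 0), c(0, 0, 1)),
                               screening_n = 2) * 4, side)
  # coincident origins are singular
  expect_error(dipole_coupling(td(c(0, 0, 0), c(0, 0, 1)),
                               td(c(0, 0, 0), c(1, 0, 0))),
               "singular geometry")
})

test_that("Hamiltonian structure: diagonal energies, zero intra-site block, symmetry", {
  dye <- build_dye_only(12500, 7)
  H1 <- build_hamiltonian(dye)
  expect_equal(H1$matrix, matrix(12500, 1, 1))

  ring2 <- build_ring(2, 0.9, 13000, 12500, 1.5, 1.1)
  H <- build_hamiltonian(ring2, screening_n = 1)
  M <- H$matrix
  expect_equal(diag(M), rep(c(13000, 12500), 2))
  expect_lt(max(abs(M - t(M))), 1e-9)
  # intra-site off-diagonals (orthogonal transitions, same centre) are zero
  expect_identical(M[1, 2], 0); expect_identical(M[3, 4], 0)
  # axial pair: side-by-side parallel dipoles, coupling mu^2 C / d^3
  td <- function(o, d, mu) transition_dipole(o, d, mu, 12500)
  vax <- dipole_coupling(td(c(0.9, 0, 0), c(0, 0, 1), 1.1),
                         td(c(-0.9, 0, 0), c(0, 0, 1), 1.1), screening_n = 1)
  expect_equal(M[2, 4], vax)
  expect_gt(M[2, 4], 0)
  # tangential pair across the diameter is antiparallel: kappa = -1
  expect_lt(M[1, 3], 0)
  # cross tangential-axial couplings vanish by symmetry
  expect_equal(M[1, 4], 0); expect_equal(M[2, 3], 0)
})

test_that("dye row couples identically to all six symmetry-equivalent ring sites", {
  m <- default_model()
  H <- build_hamiltonian(m$geometry$A,
                         screening_n = m$config$environment$screening_n)
  tr <- H$basis
  dye <- which(tr$role == "dye")
  vax <- H$matrix[dye, tr$label == "ring-axial"]
  vtg <- H$matrix[dye, tr$label == "ring-tangential"]
  expect_equal(max(abs(vax - vax[1])), 0, tolerance = 1e-12)
  expect_gt(abs(vax[1]), 1)
  # axial dye is orthogonal to every tangential transition (kappa = 0)
  expect_true(all(abs(vtg) < 1e-12))
})

test_that("dimer eigenstructure: splitting 2V, H-aggregate dark lower state", {
  E <- 12800; V <- 35
  basis <- data.frame(site = 0:1, role = "ring", label = "ring-axial",
                      x = c(0, 1), y = 0, z = 0, dx = 0, dy = 0, dz = 1,
                      mu_D = 2, E_cm1 = E, stringsAsFactors = FALSE)
  st <- diagonalize(exciton_hamiltonian(matrix(c(E, V, V, E), 2, 2), basis))
  expect_equal(st$energies, c(E - V, E + V), tolerance = 1e-12)
  # parallel side-by-side dipoles, V > 0: all strength in the upper state
  expect_equal(st$dipole_strengths[1], 0, tolerance = 1e-9)
  expect_equal(st$dipole_strengths[2], 2 * 2^2, tolerance = 1e-9)
})

test_that("dipole-strength sum rule holds for arbitrary geometries", {
  for (seed in c(1, 2, 3, 7, 19)) {
    g <- random_assembly(seed)
    st <- diagonalize(build_hamiltonian(g))
    expect_equal(sum(st$dipole_strengths), sum(g$transitions$mu_D^2),
                 tolerance = 1e-6)
    # coefficients orthonormal
    C <- st$coefficients
    expect_lt(max(abs(crossprod(C) - diag(ncol(C)))), 1e-8)
  }
})

test_that("couplings decay as R^-3 and eigenvalues ignore basis order", {
  g <- random_assembly(5)
  H <- build_hamiltonian(g)
  g2 <- g
  g2$transitions[, c("x", "y", "z")] <- 2 * g2$transitions[, c("x", "y", "z")]
  g2$ring_radius <- 2 * g2$ring_radius
  g2$dye_offset <- 2 * g2$dye_offset
  H2 <- build_hamiltonian(g2)
  off <- upper.tri(H$matrix)
  nz <- off & abs(H$matrix) > 1e-12
  expect_true(all(abs(H2$matrix[nz] * 8 / H$matrix[nz] - 1) < 1e-9))

  perm <- sample(nrow(g$transitions))
  gp <- g
  gp$transitions <- gp$transitions[perm, ]
  ep <- diagonalize(build_hamiltonian(gp))$energies
  expect_equal(ep, diagonalize(H)$energies, tolerance = 1e-9)
})

test_that("band grouping and dye-band couplings follow the block structure", {
  m <- default_model()
  sn <- m$config$environment$screening_n
  Hfull <- build_hamiltonian(m$geometry$A, screening_n = sn)
  ring_states <- diagonalize(build_hamiltonian(m$geometry$ring,
                                               screening_n = sn))
  prof <- dye_band_couplings(Hfull, ring_states, band_tol = 50)
  expect_s3_class(prof, "coupling_profile")
  expect_equal(nrow(prof), 2L)  # axial and tangential manifolds
  # the dye couples to the lowest (810 nm) band only; the tangential band is
  # symmetry-dark to the axial dye
  low <- which.max(prof$band_center_nm)
  expect_gt(prof$V_cm1[low], 1)
  expect_lt(prof$V_cm1[-low], 1e-10)
  # root-sum-square over all ring eigenstates equals sqrt(6) * site coupling
  dye <- which(Hfull$basis$role == "dye")
  vsite <- Hfull$matrix[dye, Hfull$basis$label == "ring-axial"][1]
  expect_equal(prof$V_cm1[low], sqrt(6) * abs(vsite), tolerance = 1e-9)
  # decoupled dye: every V_b = 0
  H0 <- build_hamiltonian(m$geometry$A, screening_n = sn,
                          dye_coupling_scale = 0)
  prof0 <- dye_band_couplings(H0, ring_states, band_tol = 50)
  expect_true(all(prof0$V_cm1 == 0))
  # missing dye is an error
  Hring <- build_hamiltonian(m$geometry$ring, screening_n = sn)
  expect_error(dye_band_couplings(Hring, ring_states), "missing dye")
})
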