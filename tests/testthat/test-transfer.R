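test_that("spectral overlap matches the closed Gaussian form and decays with detuning", {
  f <- 350
  same <- spectral_overlap(spectral_line(12500, f), spectral_line(12500, f))
  # Gaussian product rule: J(0) = sqrt(2 ln 2 / pi) / f = 0.66428/f
  expect_equal(same, sqrt(2 * log(2) / pi) / f, tolerance = 1e-9)
  # numerically integrated oracle
  sg <- f / (2 * sqrt(2 * log(2)))
  num <- integrate(function(E) dnorm(E, 12500, sg) * dnorm(E, 12500, sg),
                   12500 - 30 * f, 12500 + 30 * f)$value
  expect_equal(same, num, tolerance = 1e-8)
  # maximal at zero detuning, symmetric, -> 0 far away
  near <- spectral_overlap(spectral_line(12600, f), spectral_line(12500, f))
  mirror <- spectral_overlap(spectral_line(12400, f), spectral_line(12500, f))
  expect_lt(near, same)
  expect_equal(near, mirror, tolerance = 1e-12)
  expect_lt(spectral_overlap(spectral_line(20000, f),
                             spectral_line(12500, f)), 1e-12)
  # mixed shapes agree with direct integration
  mixed <- spectral_overlap(spectral_line(12500, f),
                            spectral_line(12600, f, "lorentzian"))
  hw <- f / 2
  num2 <- integrate(function(E) dnorm(E, 12500, sg) *
                      (hw / pi) / ((E - 12600)^2 + hw^2),
                    12500 - 60 * f, 12500 + 60 * f)$value
  expect_equal(mixed, num2, tolerance = 1e-6)
})

test_that("golden-rule rate is quadratic in the coupling and zero at V = 0", {
  J <- 1.9e-3
  expect_identical(golden_rule_rate(0, J), 0)
  expect_equal(golden_rule_rate(20, J) / golden_rule_rate(10, J), 4,
               tolerance = 1e-12)
  expect_error(golden_rule_rate(-1, J), "invalid parameter")
})

test_that("golden rule matches exact Weisskopf-Wigner decay in the weak-coupling regime", {
  V <- 10; Gamma <- 200
  k_exact <- ww_exact_rate(V, Gamma)
  # donor is sharp on the scale of the acceptor density: J = L_Gamma(0)
  J <- (Gamma / (2 * pi)) / (Gamma / 2)^2
  k_gr <- golden_rule_rate(V, J)
  expect_lt(abs(k_exact - k_gr) / k_gr, 0.05)
})

test_that("transfer result integrates couplings and overlaps per band", {
  m <- default_model()
  trA <- m$transfer$A
  expect_equal(trA$total_rate_ps_inv, sum(trA$per_band$k_ps_inv),
               tolerance = 1e-9)
  expect_equal(trA$transfer_time_ps, 1 / trA$total_rate_ps_inv)
  expect_false(trA$zero_rate)
  # decoupled dye: zero total rate, infinite (flagged) transfer time
  tr0 <- transfer_result(m$geometry$A, m$lineshape, dye_coupling_scale = 0)
  expect_identical(tr0$total_rate_ps_inv, 0)
  expect_identical(tr0$transfer_time_ps, Inf)
  expect_true(tr0$zero_rate)
  # rate increases monotonically as the donor line moves into resonance:
  # a larger Stokes shift lowers the donor emission towards the 810 nm band
  stokes <- c(400, 700, 1000, 1300)
  rates <- vapply(stokes, function(s)
    transfer_result(m$geometry$A, m$lineshape,
                    stokes_shift_cm1 = s)$total_rate_ps_inv, numeric(1))
  expect_true(all(diff(rates) > 0))
  # a ring without dye cannot transfer
  expect_error(transfer_result(m$geometry$ring, m$lineshape), "missing dye")
})

test_that("transfer time is invariant under rigid rotation of the assembly", {
  m <- default_model()
  t0 <- m$transfer$A$transfer_time_ps
  for (ang in c(35, 120)) {
    g <- rotate_assembly(m$geometry$A, ang, c(1, 2, 0.5))
    t1 <- transfer_result(g, m$lineshape,
                          screening_n = m$config$environment$screening_n,
                          stokes_shift_cm1 =
                            m$config$transfer$stokes_shift_cm1)$transfer_time_ps
    expect_equal(t1, t0, tolerance = 1e-6)
  }
})

test_that("degenerate ensembles reproduce the single-geometry result", {
  m <- default_model()
  dm <- disorder_model(0, 8, seed = 5)
  dist <- transfer_distribution(conformer_ensemble(m$geometry$A), dm,
                                lp = m$lineshape,
                                stokes_shift_cm1 =
                                  m$config$transfer$stokes_shift_cm1,
                                screening_n =
                                  m$config$environment$screening_n)
  expect_equal(unique(dist$samples_ps), m$transfer$A$transfer_time_ps,
               tolerance = 1e-12)
})

test_that("distribution sampling equals per-realization transfer results", {
  m <- default_model()
  gA <- m$geometry$A
  dm <- disorder_model(50, 6, seed = 99)
  dist <- transfer_distribution(conformer_ensemble(gA), dm, lp = m$lineshape)
  direct <- vapply(sample_disorder(gA, dm), function(g)
    transfer_result(g, m$lineshape)$transfer_time_ps, numeric(1))
  expect_equal(dist$samples_ps, direct, tolerance = 1e-12)
})

test_that("fixed seeds give bit-identical ensembles and summaries are self-consistent", {
  m <- default_model()
  d1 <- simulate(m, nsim = 150, seed = 31)
  d2 <- simulate(m, nsim = 150, seed = 31)
  expect_identical(d1$samples_ps, d2$samples_ps)
  expect_identical(d1$conformer, d2$conformer)
  # summary definitions
  expect_equal(d1$median_ps, median(d1$samples_ps))
  expect_equal(d1$mean_rate_ps_inv, mean(1 / d1$samples_ps), tolerance = 1e-12)
  expect_equal(d1$p_within_50ps, mean(d1$samples_ps < 50))
  # prob_within is the empirical CDF: monotone, ends at 1
  Ts <- c(0.5, 1, 2, 5, 10, 50, Inf)
  ps <- prob_within(d1, Ts)
  expect_true(all(diff(ps) >= 0))
  expect_equal(ps[length(ps)], 1)
  expect_equal(ps[6], d1$p_within_50ps)
  # both conformers appear under Boltzmann draws at n = 150
  expect_setequal(unique(d1$conformer), c("A", "B"))
})
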