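test_that("ring sites sit at equal angular spacing with tangential/axial transitions", {
  r <- 1.2
  ring <- build_ring(6, r, 13158, 12345, 0.38, 0.53)
  tr <- ring$transitions
  expect_equal(nrow(tr), 12L)
  expect_equal(length(unique(tr$site)), 6L)
  # positions on the circle at 60 deg spacing
  ax <- tr[tr$label == "ring-axial", ]
  th <- atan2(ax$y, ax$x) %% (2 * pi)
  expect_equal(sort(th), 2 * pi * (0:5) / 6, tolerance = 1e-12)
  # equidistant from the z axis
  expect_true(all(abs(sqrt(tr$x^2 + tr$y^2) - r) < 1e-9))
  # tangential direction perpendicular to the radial vector
  tg <- tr[tr$label == "ring-tangential", ]
  dots <- tg$dx * tg$x + tg$dy * tg$y + tg$dz * tg$z
  expect_true(all(abs(dots) < 1e-9))
  # axial and tangential directions mutually orthogonal, unit length
  expect_true(all(abs(tr$dx^2 + tr$dy^2 + tr$dz^2 - 1) < 1e-12))
})

test_that("a two-site ring spans its diameter", {
  ring <- build_ring(2, 0.9, 13000, 12500, 1, 1)
  ax <- ring$transitions[ring$transitions$label == "ring-axial", ]
  d <- sqrt(diff(ax$x)^2 + diff(ax$y)^2 + diff(ax$z)^2)
  expect_equal(d, 1.8, tolerance = 1e-12)
})

test_that("invalid ring parameters are rejected", {
  expect_error(build_ring(1, 1.2, 13000, 12500, 1, 1), "invalid parameter")
  expect_error(build_ring(6, -1, 13000, 12500, 1, 1), "invalid parameter")
  expect_error(build_ring(6, 1.2, 13000, 12500, 0, 1), "invalid parameter")
  expect_error(build_ring(6, 1.2, -5, 12500, 1, 1), "invalid parameter")
})

test_that("dye placement follows the conformer convention", {
  ring <- build_ring(6, 1.2, 13158, 12345, 0.38, 0.53)
  gA <- add_dye(ring, "A", 0.4, 13793, 11)
  gB <- add_dye(ring, "B", 0.4, 13793, 11)
  dyeA <- gA$transitions[gA$transitions$role == "dye", ]
  dyeB <- gB$transitions[gB$transitions$role == "dye", ]
  expect_equal(unlist(dyeA[, c("x", "y", "z")], use.names = FALSE), c(0, 0, 0))
  expect_equal(unlist(dyeB[, c("x", "y", "z")], use.names = FALSE),
               c(0, 0, 0.4))
  # dye polarised along the ring axis, orthogonal to every tangential dipole
  expect_equal(unlist(dyeA[, c("dx", "dy", "dz")], use.names = FALSE),
               c(0, 0, 1))
  tg <- gA$transitions[gA$transitions$label == "ring-tangential", ]
  expect_true(all(abs(tg$dx * dyeA$dx + tg$dy * dyeA$dy + tg$dz * dyeA$dz)
                  < 1e-12))
  # second dye and zero offset for B are rejected
  expect_error(add_dye(gA, "A", 0.4, 13793, 11), "duplicate dye")
  expect_error(add_dye(ring, "B", 0, 13793, 11), "invalid parameter")
})

test_that("conformer A retains the ring's six-fold symmetry", {
  m <- default_model()
  g <- m$geometry$A
  rot <- rotate_assembly(g, 60)
  key <- function(a) {
    tr <- a$transitions
    o <- order(tr$label, round(atan2(tr$y, tr$x), 9))
    round(as.matrix(tr[o, c("x", "y", "z", "dx", "dy", "dz", "mu_D",
                            "E_cm1")]), 9)
  }
  expect_equal(unname(key(rot)), unname(key(g)))
})

test_that("disorder sampling is reproducible, mean-preserving and correctly scaled", {
  dye <- build_dye_only(13000, 5)
  # zero disorder: all realizations identical to the input
  r0 <- sample_disorder(dye, disorder_model(0, 5, seed = 3))
  for (g in r0) expect_identical(g$transitions$E_cm1, 13000)
  # same seed twice: bitwise identical energies
  dm <- disorder_model(100, 50, seed = 11)
  e1 <- vapply(sample_disorder(dye, dm), function(g) g$transitions$E_cm1, 1)
  e2 <- vapply(sample_disorder(dye, dm), function(g) g$transitions$E_cm1, 1)
  expect_identical(e1, e2)
  # law of large numbers: sample SD within 3% of sigma at n = 10000,
  # sample mean within 3 sigma / sqrt(n) of the undisordered energy
  dmL <- disorder_model(100, 10000, seed = 4)
  eL <- vapply(sample_disorder(dye, dmL), function(g) g$transitions$E_cm1, 1)
  expect_lt(abs(sd(eL) - 100) / 100, 0.03)
  expect_lt(abs(mean(eL) - 13000), 3 * 100 / sqrt(10000))
  # the caller's RNG stream is untouched
  set.seed(42); before <- rnorm(1)
  set.seed(42); invisible(sample_disorder(dye, dm)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("conformer ensemble weights follow the Boltzmann factor", {
  m <- default_model()
  ens <- conformer_ensemble(list(m$geometry$A, m$geometry$B),
                            delta_E = 0.7, temperature = 298.15)
  expect_equal(sum(ens$weights), 1)
  expect_equal(ens$weights[2] / ens$weights[1],
               exp(-0.7 / (8.314462618e-3 * 298.15)), tolerance = 1e-12)
  # approximately 57:43
  expect_equal(ens$weights[1], 0.57, tolerance = 0.01)
  expect_equal(conformer_ensemble(m$geometry$A)$weights, 1)
})

test_that("geometry JSON round trip preserves the assembly", {
  g <- default_model()$geometry$B
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  write_geometry_json(g, path)
  g2 <- read_geometry_json(path)
  expect_equal(g2$transitions, g$transitions, tolerance = 1e-12)
  expect_identical(g2$conformer, g$conformer)
  expect_equal(g2$ring_radius, g$ring_radius)
  expect_equal(g2$dye_offset, g$dye_offset)
})
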