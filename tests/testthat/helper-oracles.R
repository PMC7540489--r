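# Shared fixtures and independent oracles.

# Memoized default calibrated model (calibration is deterministic, so one
# instance serves every file).
default_model <- local({
  m <- NULL
  function() {
    if (is.null(m)) m <<- lh_model()
    m
  }
})

# Independent Weisskopf-Wigner oracle: exact unitary dynamics of one donor
# level coupled to a dense equidistant manifold whose coupling density
# reproduces a unit-area Lorentzian of FWHM `Gamma`. Returns the fitted
# exponential decay rate of the donor survival probability (ps^-1). Built
# directly on base eigen(), independent of the package's rate pipeline.
ww_exact_rate <- function(V, Gamma, W = 2400, delta = 2,
                          t_fit = seq(0.5, 5, by = 0.25)) {
  Eb <- seq(-W / 2, W / 2, by = delta)
  L <- (Gamma / (2 * pi)) / (Eb^2 + (Gamma / 2)^2)
  v <- V * sqrt(delta * L)
  n <- length(Eb) + 1L
  H <- matrix(0, n, n)
  H[1, 2:n] <- v
  H[2:n, 1] <- v
  diag(H)[2:n] <- Eb
  ev <- eigen(H, symmetric = TRUE)
  w2 <- ev$vectors[1, ]^2
  cps <- 2.99792458e-2
  P <- vapply(t_fit, function(t)
    Mod(sum(w2 * exp(-2i * pi * cps * ev$values * t)))^2, numeric(1))
  -unname(stats::coef(stats::lm(log(P) ~ t_fit))[2])
}

# Two-level toy Hamiltonian on an explicit basis (orthogonal dipoles so the
# dye-state dipole gain is purely second order in V / Delta).
toy_two_level <- function(V, E_dye = 13000, E_ring = 12500,
                          mu_dye = 5, mu_ring = 2) {
  basis <- data.frame(site = 0:1, role = c("dye", "ring"),
                      label = c("dye", "ring-axial"),
                      x = c(0, 1), y = 0, z = 0,
                      dx = c(0, 0), dy = c(0, 1), dz = c(1, 0),
                      mu_D = c(mu_dye, mu_ring), E_cm1 = c(E_dye, E_ring),
                      stringsAsFactors = FALSE)
  exciton_hamiltonian(matrix(c(E_dye, V, V, E_ring), 2, 2), basis)
}

# Randomized assembly for property-style loops: ring of random size and
# parameters, optionally rotated and carrying a dye.
random_assembly <- function(seed, with_dye = TRUE) {
  set.seed(seed)
  ring <- build_ring(sample(3:8, 1), runif(1, 0.8, 2.5),
                     runif(1, 12000, 14000), runif(1, 11500, 13500),
                     runif(1, 0.3, 6), runif(1, 0.3, 6))
  g <- if (with_dye)
    add_dye(ring, sample(c("A", "B"), 1), runif(1, 0.2, 0.6),
            runif(1, 12500, 14500), runif(1, 3, 12))
  else ring
  rotate_assembly(g, runif(1, 0, 360), stats::rnorm(3))
}
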