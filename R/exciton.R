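# Frenkel exciton core: point-dipole couplings, Hamiltonian assembly,
# diagonalization, and dye-band coupling profiles.

#' Point-dipole coupling between two transition dipoles
#'
#' Evaluates the dipole-dipole interaction
#' `V = kappa * mu1 * mu2 * C / (n^2 R^3)` in cm^-1, with orientation factor
#' `kappa = d1.d2 - 3 (d1.R)(d2.R)` (unit vectors), `R` the centre-to-centre
#' distance in nm, dipoles in Debye and `C` the SI-derived conversion
#' constant (5.0341 cm^-1 for 1 D, 1 D at 1 nm in vacuum). Dielectric
#' screening by the solvent enters as `1/n^2`.
#'
#' @param d1,d2 [transition_dipole()] objects (or lists with `origin`,
#'   `direction`, `magnitude`) at distinct origins.
#' @param screening_n Medium refractive index (default 1.424, CH2Cl2).
#' @return Coupling in cm^-1 (signed).
#' @examples
#' a <- transition_dipole(c(0, 0, 0), c(0, 0, 1), 1, 13000)
#' b <- transition_dipole(c(1, 0, 0), c(0, 0, 1), 1, 13000)
#' dipole_coupling(a, b, screening_n = 1)  # ~ 5.03 cm^-1 (side-by-side)
#' @export
dipole_coupling <- function(d1, d2, screening_n = 1.424) {
  R <- as.numeric(d2$origin) - as.numeric(d1$origin)
  Rn <- sqrt(sum(R^2))
  if (Rn < 1e-9)
    stop("singular geometry: coincident dipole origins")
  if (!is.numeric(screening_n) || screening_n <= 0)
    stop("invalid parameter: 'screening_n' must be positive")
  Rh <- R / Rn
  u1 <- as.numeric(d1$direction); u1 <- u1 / sqrt(sum(u1^2))
  u2 <- as.numeric(d2$direction); u2 <- u2 / sqrt(sum(u2^2))
  kappa <- sum(u1 * u2) - 3 * sum(u1 * Rh) * sum(u2 * Rh)
  .dipole_prefactor_cm1 * kappa * d1$magnitude * d2$magnitude /
    (screening_n^2 * Rn^3)
}

#' Low-level exciton Hamiltonian constructor
#'
#' Wraps an explicit real symmetric matrix (site energies on the diagonal,
#' couplings off it, both in cm^-1) together with its basis bookkeeping.
#' Mostly used internally and by reduced toy models in tests; ordinary use
#' goes through [build_hamiltonian()].
#'
#' @param matrix Real symmetric matrix (cm^-1).
#' @param basis Data frame describing the basis transitions (one row each);
#'   any columns, but `role` and the dipole columns `dx, dy, dz, mu_D` are
#'   needed for state dipoles and dye bookkeeping.
#' @param screening_n Medium refractive index recorded with the model.
#' @return An object of class `exciton_hamiltonian`.
#' @export
exciton_hamiltonian <- function(matrix, basis, screening_n = 1.424) {
  stopifnot(is.matrix(matrix), nrow(matrix) == ncol(matrix))
  if (max(abs(matrix - t(matrix))) > 1e-9)
    stop("invalid parameter: Hamiltonian matrix must be symmetric")
  stopifnot(is.data.frame(basis), nrow(basis) == nrow(matrix))
  structure(list(matrix = matrix, basis = basis, screening_n = screening_n),
            class = "exciton_hamiltonian")
}

#' Build the Frenkel exciton Hamiltonian of an assembly
#'
#' Diagonal entries are the site energies of the basis transitions;
#' off-diagonal entries are point-dipole couplings between transitions on
#' different sites. The two orthogonal transitions of one porphyrin share an
#' origin (point-dipole coupling undefined at R = 0) and are set to zero
#' coupling.
#'
#' @param geom An `assembly`.
#' @param screening_n Medium refractive index (default 1.424, CH2Cl2).
#' @param dye_coupling_scale Scale factor applied to the dye-ring coupling
#'   block (default 1). `0` decouples the dye exactly, giving a
#'   block-diagonal Hamiltonian; intermediate values support perturbative
#'   probes of spectral additivity and dipole redistribution.
#' @return An `exciton_hamiltonian`.
#' @examples
#' ring <- build_ring(6, 1.2, 13158, 12345, 0.38, 0.53)
#' H <- build_hamiltonian(ring)
#' @export
build_hamiltonian <- function(geom, screening_n = 1.424,
                              dye_coupling_scale = 1) {
  stopifnot(inherits(geom, "assembly"))
  tr <- geom$transitions
  n <- nrow(tr)
  if (n < 1L) stop("invalid parameter: assembly has no transitions")
  H <- diag(tr$E_cm1, n, n)
  if (n > 1L) {
    pos <- as.matrix(tr[, c("x", "y", "z")])
    dir <- as.matrix(tr[, c("dx", "dy", "dz")])
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        if (tr$site[i] == tr$site[j]) next  # same chromophore: 0 by convention
        v <- dipole_coupling(
          list(origin = pos[i, ], direction = dir[i, ],
               magnitude = tr$mu_D[i]),
          list(origin = pos[j, ], direction = dir[j, ],
               magnitude = tr$mu_D[j]),
          screening_n = screening_n)
        if (xor(tr$role[i] == "dye", tr$role[j] == "dye"))
          v <- v * dye_coupling_scale
        H[i, j] <- H[j, i] <- v
      }
    }
  }
  exciton_hamiltonian(H, tr, screening_n)
}

#' @export
print.exciton_hamiltonian <- function(x, ...) {
  cat(sprintf("<exciton Hamiltonian> %d x %d, screening n = %.3f\n",
              nrow(x$matrix), ncol(x$matrix), x$screening_n))
  offd <- x$matrix[upper.tri(x$matrix)]
  cat(sprintf("  diagonal %.1f..%.1f cm^-1, |coupling| up to %.2f cm^-1\n",
              min(diag(x$matrix)), max(diag(x$matrix)),
              if (length(offd)) max(abs(offd)) else 0))
  invisible(x)
}

#' Diagonalize an exciton Hamiltonian
#'
#' Returns the exciton states in ascending energy order with orthonormal
#' coefficient columns. Each state's transition dipole is the coefficient-
#' weighted vector sum of the basis dipoles,
#' `mu_k = sum_i c_ik mu_i`, so the total dipole strength
#' `sum_k |mu_k|^2` equals `sum_i |mu_i|^2` exactly (orthogonality sum rule).
#'
#' @param H An `exciton_hamiltonian`.
#' @return An object of class `exciton_states` with elements `energies`
#'   (cm^-1, ascending), `coefficients` (columns = states),
#'   `state_dipoles` (n x 3, Debye), `dipole_strengths` (Debye^2) and the
#'   basis data frame.
#' @examples
#' ring <- build_ring(6, 1.2, 13158, 12345, 0.38, 0.53)
#' st <- diagonalize(build_hamiltonian(ring))
#' sum(st$dipole_strengths)  # equals sum of squared basis dipoles
#' @export
diagonalize <- function(H) {
  stopifnot(inherits(H, "exciton_hamiltonian"))
  ev <- eigen(H$matrix, symmetric = TRUE)
  ord <- order(ev$values)          # eigen() returns decreasing order
  energies <- ev$values[ord]
  coeff <- ev$vectors[, ord, drop = FALSE]
  mu_basis <- as.matrix(H$basis[, c("dx", "dy", "dz")]) * H$basis$mu_D
  state_dipoles <- t(mu_basis) %*% coeff            # 3 x n
  strengths <- colSums(state_dipoles^2)
  structure(list(energies = energies, coefficients = coeff,
                 state_dipoles = t(state_dipoles),
                 dipole_strengths = strengths, basis = H$basis),
            class = "exciton_states")
}

#' @export
print.exciton_states <- function(x, ...) {
  cat(sprintf("<exciton states> %d states, %.1f..%.1f cm^-1 (%.1f..%.1f nm)\n",
              length(x$energies), min(x$energies), max(x$energies),
              cm1_to_nm(max(x$energies)), cm1_to_nm(min(x$energies))))
  bright <- x$dipole_strengths > 1e-6
  cat(sprintf("  %d bright state(s); total dipole strength %.3f D^2\n",
              sum(bright), sum(x$dipole_strengths)))
  invisible(x)
}

# Group ascending energies into bands: consecutive states closer than `tol`
# belong to the same band (single linkage). Returns a list of index vectors.
.group_bands <- function(energies, tol) {
  stopifnot(!is.unsorted(energies))
  n <- length(energies)
  if (n == 0L) return(list())
  brk <- which(diff(energies) > tol)
  starts <- c(1L, brk + 1L)
  ends <- c(brk, n)
  mapply(function(s, e) s:e, starts, ends, SIMPLIFY = FALSE)
}

#' Dye-to-band coupling profile
#'
#' For each band of near-degenerate ring exciton states, computes the
#' root-sum-square coupling between the dye basis state and the band's
#' eigenstates: `V_b = sqrt(sum_{k in b} |<dye|H|k>|^2)` with
#' `<dye|H|k> = sum_i c_ik H[dye, i]`. Band centres are the coupling-weighted
#' mean state energies (falling back to the plain mean for dark, uncoupled
#' bands), reported as wavelengths.
#'
#' @param H Full-assembly `exciton_hamiltonian` containing exactly one dye
#'   transition.
#' @param ring_states `exciton_states` of the corresponding ring-only
#'   Hamiltonian (same ring transition order as in `H`).
#' @param band_tol Band grouping tolerance in cm^-1: adjacent eigenstates
#'   closer than this are merged into one band (default 50, far below the
#'   inter-band spacing of the Q-band system).
#' @return A `coupling_profile`: data frame with columns `band_center_nm`,
#'   `V_cm1` and `k_ps_inv` (rates `NA` until filled by [transfer_result()]).
#' @export
dye_band_couplings <- function(H, ring_states, band_tol = 50) {
  stopifnot(inherits(H, "exciton_hamiltonian"),
            inherits(ring_states, "exciton_states"))
  dye_idx <- which(H$basis$role == "dye")
  if (length(dye_idx) == 0L)
    stop("missing dye: assembly Hamiltonian has no dye transition")
  if (length(dye_idx) > 1L)
    stop("invalid parameter: more than one dye transition")
  ring_idx <- which(H$basis$role != "dye")
  if (length(ring_idx) != length(ring_states$energies))
    stop("invalid parameter: ring_states basis does not match Hamiltonian")
  hrow <- H$matrix[dye_idx, ring_idx]
  Vk <- as.numeric(crossprod(ring_states$coefficients, hrow))
  bands <- .group_bands(ring_states$energies, band_tol)
  out <- do.call(rbind, lapply(bands, function(idx) {
    v2 <- Vk[idx]^2
    center <- if (sum(v2) > 0)
      sum(v2 * ring_states$energies[idx]) / sum(v2)
    else mean(ring_states$energies[idx])
    data.frame(band_center_nm = cm1_to_nm(center),
               V_cm1 = sqrt(sum(v2)), k_ps_inv = NA_real_)
  }))
  structure(out, class = c("coupling_profile", "data.frame"))
}

#' @export
print.coupling_profile <- function(x, ...) {
  cat("<dye-band coupling profile>\n")
  print.data.frame(format(as.data.frame(x), digits = 4), row.names = FALSE)
  invisible(x)
}
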