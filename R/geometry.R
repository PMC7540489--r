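# Synthetic geometry generation: ring of porphyrin-like sites + axial dye,
# conformers A/B, and static-disorder realizations.
#
# Coordinate convention: ring plane is z = 0, ring axis is +z, site 0 sits on
# the +x axis. All positions in nm.
#
# An assembly is a light S3 object whose `transitions` element is a flat
# data frame with one row per optical transition:
#   site (int), role ("ring"/"dye"), label, x, y, z, dx, dy, dz, mu_D, E_cm1

#' Construct a single transition dipole
#'
#' A transition dipole is the elementary optical degree of freedom of the
#' model: a point dipole with an origin (nm), a unit direction, a magnitude in
#' Debye and a site transition energy in wavenumbers.
#'
#' @param origin Numeric length-3 position in nm.
#' @param direction Numeric length-3 direction; normalised internally.
#' @param magnitude Dipole strength in Debye; must be positive.
#' @param site_energy Transition energy in cm^-1; must be positive.
#' @param label Free-text label (e.g. `"ring-tangential"`, `"dye"`).
#' @return An object of class `transition_dipole` (a named list).
#' @examples
#' transition_dipole(c(1.2, 0, 0), c(0, 1, 0), 1.5, 13000, "ring-tangential")
#' @export
transition_dipole <- function(origin, direction, magnitude, site_energy,
                              label = "") {
  if (!is.numeric(origin) || length(origin) != 3L || any(!is.finite(origin)))
    stop("invalid parameter: 'origin' must be a finite length-3 numeric")
  if (!is.numeric(direction) || length(direction) != 3L ||
      any(!is.finite(direction)))
    stop("invalid parameter: 'direction' must be a finite length-3 numeric")
  nrm <- sqrt(sum(direction^2))
  if (nrm < 1e-12)
    stop("invalid parameter: 'direction' has (near) zero length")
  if (!is.numeric(magnitude) || length(magnitude) != 1L || magnitude <= 0)
    stop("invalid parameter: 'magnitude' must be a single positive number")
  if (!is.numeric(site_energy) || length(site_energy) != 1L || site_energy <= 0)
    stop("invalid parameter: 'site_energy' must be a single positive number")
  structure(
    list(origin = as.numeric(origin), direction = as.numeric(direction) / nrm,
         magnitude = as.numeric(magnitude),
         site_energy = as.numeric(site_energy), label = as.character(label)),
    class = "transition_dipole")
}

#' @export
print.transition_dipole <- function(x, ...) {
  cat(sprintf(
    "<transition dipole '%s'>  mu = %.3g D, E = %.1f cm^-1 (%.1f nm)\n",
    x$label, x$magnitude, x$site_energy, cm1_to_nm(x$site_energy)))
  cat(sprintf("  origin    (%.4g, %.4g, %.4g) nm\n",
              x$origin[1], x$origin[2], x$origin[3]))
  cat(sprintf("  direction (%.4g, %.4g, %.4g)\n",
              x$direction[1], x$direction[2], x$direction[3]))
  invisible(x)
}

.assembly <- function(transitions, conformer, ring_radius, dye_offset = 0) {
  structure(list(transitions = transitions, conformer = conformer,
                 ring_radius = ring_radius, dye_offset = dye_offset),
            class = "assembly")
}

.td_row <- function(site, role, label, origin, direction, mu, E) {
  data.frame(site = site, role = role, label = label,
             x = origin[1], y = origin[2], z = origin[3],
             dx = direction[1], dy = direction[2], dz = direction[3],
             mu_D = mu, E_cm1 = E, stringsAsFactors = FALSE)
}

#' Build the bare chromophore ring
#'
#' Places `n_sites` porphyrin-like sites on a circle of radius `ring_radius`
#' in the z = 0 plane, at equal angular spacing with site 0 on the +x axis.
#' Each site carries two mutually orthogonal Q-type transitions: one tangent
#' to the ring circle and one parallel to the ring axis (+z). The two
#' transitions make the model able to produce a multi-band ring spectrum and
#' a symmetry-allowed coupling to an axial dye.
#'
#' @param n_sites Number of ring sites (>= 2; the physical assembly has 6).
#' @param ring_radius Ring radius in nm (centre-to-zinc distance).
#' @param site_energy_tangential,site_energy_axial Site energies (cm^-1) of
#'   the tangential and axial transitions.
#' @param mu_tangential,mu_axial Transition dipole magnitudes (Debye).
#' @return An `assembly` with `conformer = "ring_only"`.
#' @examples
#' ring <- build_ring(6, 1.2, 13158, 12345, 0.38, 0.53)
#' ring
#' @seealso [add_dye()], [default_config()] for the calibrated defaults.
#' @export
build_ring <- function(n_sites, ring_radius, site_energy_tangential,
                       site_energy_axial, mu_tangential, mu_axial) {
  if (!is.numeric(n_sites) || length(n_sites) != 1L || n_sites < 2 ||
      n_sites != round(n_sites))
    stop("invalid parameter: 'n_sites' must be an integer >= 2")
  if (!is.numeric(ring_radius) || length(ring_radius) != 1L || ring_radius <= 0)
    stop("invalid parameter: 'ring_radius' must be positive")
  for (v in c(site_energy_tangential, site_energy_axial,
              mu_tangential, mu_axial))
    if (!is.numeric(v) || length(v) != 1L || v <= 0)
      stop("invalid parameter: energies and dipole magnitudes must be positive")
  theta <- 2 * pi * (seq_len(n_sites) - 1L) / n_sites
  rows <- vector("list", 2L * n_sites)
  for (k in seq_len(n_sites)) {
    pos <- c(ring_radius * cos(theta[k]), ring_radius * sin(theta[k]), 0)
    tangent <- c(-sin(theta[k]), cos(theta[k]), 0)
    rows[[2L * k - 1L]] <- .td_row(k - 1L, "ring", "ring-tangential", pos,
                                   tangent, mu_tangential,
                                   site_energy_tangential)
    rows[[2L * k]] <- .td_row(k - 1L, "ring", "ring-axial", pos, c(0, 0, 1),
                              mu_axial, site_energy_axial)
  }
  .assembly(do.call(rbind, rows), "ring_only", ring_radius)
}

#' Thread the axial dye through the ring
#'
#' Adds the cyanine dye as a single transition on the ring axis, polarised
#' along +z. Conformer A centres the dye in the plane of the metal centres
#' (origin at 0); conformer B shifts it towards one rim of the ring by
#' `axial_offset_B`.
#'
#' @param geom A `ring_only` assembly from [build_ring()].
#' @param conformer `"A"` (centred) or `"B"` (rim-shifted).
#' @param axial_offset_B Axial displacement of the dye in nm; used only for
#'   conformer B, where it must be positive.
#' @param dye_energy Dye transition energy (cm^-1).
#' @param dye_mu Dye transition dipole magnitude (Debye).
#' @return An `assembly` with the dye site appended.
#' @examples
#' ring <- build_ring(6, 1.2, 13158, 12345, 0.38, 0.53)
#' add_dye(ring, "A", 0.4, nm_to_cm1(725), 11)
#' @export
add_dye <- function(geom, conformer = c("A", "B"), axial_offset_B = 0.4,
                    dye_energy, dye_mu) {
  stopifnot(inherits(geom, "assembly"))
  conformer <- match.arg(conformer)
  if (any(geom$transitions$role == "dye"))
    stop("duplicate dye site: assembly already contains a dye")
  if (geom$conformer != "ring_only")
    stop("invalid parameter: 'geom' must be a ring_only assembly")
  if (conformer == "B" &&
      (!is.numeric(axial_offset_B) || axial_offset_B <= 0))
    stop("invalid parameter: 'axial_offset_B' must be positive for conformer B")
  if (!is.numeric(dye_energy) || dye_energy <= 0 ||
      !is.numeric(dye_mu) || dye_mu <= 0)
    stop("invalid parameter: dye energy and dipole must be positive")
  offset <- if (conformer == "A") 0 else axial_offset_B
  dye <- .td_row(max(geom$transitions$site) + 1L, "dye", "dye",
                 c(0, 0, offset), c(0, 0, 1), dye_mu, dye_energy)
  .assembly(rbind(geom$transitions, dye), conformer, geom$ring_radius, offset)
}

#' Build a dye-only assembly
#'
#' A single-transition assembly holding just the axial dye; used for the
#' component spectra entering the additivity analysis and as a minimal
#' calibration fixture.
#'
#' @inheritParams add_dye
#' @return An `assembly` with `conformer = "dye_only"`.
#' @export
build_dye_only <- function(dye_energy, dye_mu) {
  if (!is.numeric(dye_energy) || dye_energy <= 0 ||
      !is.numeric(dye_mu) || dye_mu <= 0)
    stop("invalid parameter: dye energy and dipole must be positive")
  dye <- .td_row(0L, "dye", "dye", c(0, 0, 0), c(0, 0, 1), dye_mu, dye_energy)
  .assembly(dye, "dye_only", NA_real_, 0)
}

#' Remove the dye from an assembly
#'
#' @param geom An assembly containing a dye site.
#' @return The corresponding `ring_only` assembly.
#' @export
remove_dye <- function(geom) {
  stopifnot(inherits(geom, "assembly"))
  keep <- geom$transitions$role != "dye"
  if (all(keep)) return(geom)
  .assembly(geom$transitions[keep, , drop = FALSE], "ring_only",
            geom$ring_radius)
}

#' @export
print.assembly <- function(x, ...) {
  tr <- x$transitions
  cat(sprintf("<assembly: conformer %s>  %d sites, %d transitions\n",
              x$conformer, length(unique(tr$site)), nrow(tr)))
  if (!is.na(x$ring_radius))
    cat(sprintf("  ring radius %.3g nm", x$ring_radius))
  if (any(tr$role == "dye"))
    cat(sprintf(", dye axial offset %.3g nm", x$dye_offset))
  cat("\n")
  for (lab in unique(tr$label)) {
    sub <- tr[tr$label == lab, ]
    cat(sprintf("  %-16s n = %d, mu = %.3g D, <E> = %.1f cm^-1 (%.1f nm)\n",
                lab, nrow(sub), sub$mu_D[1], mean(sub$E_cm1),
                cm1_to_nm(mean(sub$E_cm1))))
  }
  invisible(x)
}

#' Rigidly rotate an assembly
#'
#' Rotates all transition origins and directions about an axis through the
#' origin (Rodrigues formula). Exciton couplings, spectra and transfer rates
#' are invariant under this operation.
#'
#' @param geom An `assembly`.
#' @param angle_deg Rotation angle in degrees.
#' @param axis Length-3 rotation axis (need not be normalised).
#' @return The rotated `assembly`.
#' @export
rotate_assembly <- function(geom, angle_deg, axis = c(0, 0, 1)) {
  stopifnot(inherits(geom, "assembly"), is.numeric(angle_deg),
            is.numeric(axis), length(axis) == 3L)
  a <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  tr <- geom$transitions
  pos <- as.matrix(tr[, c("x", "y", "z")]) %*% t(R)
  dir <- as.matrix(tr[, c("dx", "dy", "dz")]) %*% t(R)
  tr[, c("x", "y", "z")] <- pos
  tr[, c("dx", "dy", "dz")] <- dir
  geom$transitions <- tr
  geom
}

#' Specify a static-disorder model
#'
#' Static (inhomogeneous) disorder is modelled as independent Gaussian shifts
#' of every transition's site energy, frozen within each realization. It
#' produces realization-to-realization scatter of transition energies and
#' hence a distribution of energy-transfer times.
#'
#' @param sigma_site Standard deviation of the site-energy shifts (cm^-1);
#'   must be >= 0.
#' @param n_realizations Number of disorder realizations (>= 1).
#' @param seed Integer RNG seed; required so that ensembles are reproducible.
#' @return An object of class `disorder_model`.
#' @examples
#' disorder_model(50, 1000, seed = 1)
#' @export
disorder_model <- function(sigma_site = 50, n_realizations = 5000, seed) {
  if (!is.numeric(sigma_site) || length(sigma_site) != 1L || sigma_site < 0)
    stop("invalid parameter: 'sigma_site' must be >= 0")
  if (!is.numeric(n_realizations) || length(n_realizations) != 1L ||
      n_realizations < 1 || n_realizations != round(n_realizations))
    stop("invalid parameter: 'n_realizations' must be an integer >= 1")
  if (missing(seed) || is.null(seed) || !is.numeric(seed) ||
      length(seed) != 1L || !is.finite(seed))
    stop("invalid parameter: 'seed' is required and must be a single integer")
  structure(list(sigma_site = sigma_site,
                 n_realizations = as.integer(n_realizations),
                 seed = as.integer(seed)),
            class = "disorder_model")
}

# Run code with a private RNG stream, restoring the caller's stream after.
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Draw the n x k matrix of site-energy shifts for a disorder model.
# Row i is realization i; columns follow the transition order of the
# assembly. Kept as a single rnorm call so sampling order is well defined.
.disorder_shifts <- function(dm, k) {
  matrix(stats::rnorm(dm$n_realizations * k, 0, dm$sigma_site),
         nrow = dm$n_realizations, ncol = k, byrow = TRUE)
}

#' Sample static-disorder realizations of an assembly
#'
#' Returns `n_realizations` copies of `geom` with independent Gaussian shifts
#' (sd `sigma_site`) added to every transition's site energy. Sampling is
#' mean-preserving and fully reproducible: the same seed yields bitwise
#' identical energy sequences, and the caller's RNG stream is left untouched.
#'
#' @param geom An `assembly`.
#' @param dm A [disorder_model()].
#' @return A list of `assembly` objects of length `n_realizations`.
#' @examples
#' ring <- build_ring(6, 1.2, 13158, 12345, 0.38, 0.53)
#' reals <- sample_disorder(ring, disorder_model(50, 3, seed = 7))
#' @export
sample_disorder <- function(geom, dm) {
  stopifnot(inherits(geom, "assembly"), inherits(dm, "disorder_model"))
  k <- nrow(geom$transitions)
  shifts <- .with_seed(dm$seed, .disorder_shifts(dm, k))
  lapply(seq_len(dm$n_realizations), function(i) {
    g <- geom
    g$transitions$E_cm1 <- g$transitions$E_cm1 + shifts[i, ]
    g
  })
}

#' Boltzmann-weighted conformer ensemble
#'
#' Combines the two low-energy conformers of the assembly (dye centred in the
#' ring plane, A, versus shifted towards one rim, B) with Boltzmann weights
#' determined by their energy gap. With the default 0.7 kJ/mol gap at 298 K
#' the populations are approximately 57:43 (A:B).
#'
#' @param geoms A single `assembly` or a list of assemblies. The first member
#'   is taken as the lowest-energy conformer.
#' @param delta_E Energy of the second conformer above the first (kJ/mol).
#' @param temperature Temperature in K.
#' @param weights Optional explicit weights (overrides the Boltzmann rule;
#'   required when more than two conformers are supplied).
#' @return An object of class `conformer_ensemble` with `members`
#'   (list of assemblies), `weights` (summing to 1), `delta_E`, `temperature`.
#' @export
conformer_ensemble <- function(geoms, delta_E = 0.7, temperature = 298.15,
                               weights = NULL) {
  if (inherits(geoms, "assembly")) geoms <- list(geoms)
  stopifnot(is.list(geoms), length(geoms) >= 1L,
            all(vapply(geoms, inherits, TRUE, "assembly")))
  if (is.null(weights)) {
    if (length(geoms) == 1L) {
      weights <- 1
    } else if (length(geoms) == 2L) {
      b <- exp(-delta_E / (.R_kJ_mol_K * temperature))
      weights <- c(1, b) / (1 + b)
    } else {
      stop("invalid parameter: explicit 'weights' required for > 2 conformers")
    }
  } else {
    if (length(weights) != length(geoms) || any(weights < 0) ||
        sum(weights) <= 0)
      stop("invalid parameter: 'weights' must be non-negative, one per member")
    weights <- weights / sum(weights)
  }
  structure(list(members = geoms, weights = weights, delta_E = delta_E,
                 temperature = temperature),
            class = "conformer_ensemble")
}

#' @export
print.conformer_ensemble <- function(x, ...) {
  cat(sprintf("<conformer ensemble> %d member(s), T = %.1f K\n",
              length(x$members), x$temperature))
  for (i in seq_along(x$members))
    cat(sprintf("  %s: weight %.3f\n", x$members[[i]]$conformer,
                x$weights[i]))
  invisible(x)
}

#' Write / read an assembly as JSON
#'
#' Geometry interchange format: one record per transition with fields
#' `site`, `role`, `label`, `origin`, `direction`, `magnitude_D`,
#' `site_energy_cm1`, plus the conformer tag, ring radius and dye offset.
#'
#' @param geom An `assembly`.
#' @param path Output (input) file path.
#' @return `write_geometry_json` returns `path` invisibly;
#'   `read_geometry_json` returns the reconstructed `assembly`.
#' @export
write_geometry_json <- function(geom, path) {
  stopifnot(inherits(geom, "assembly"))
  tr <- geom$transitions
  recs <- lapply(seq_len(nrow(tr)), function(i) list(
    site = tr$site[i], role = tr$role[i], label = tr$label[i],
    origin = c(tr$x[i], tr$y[i], tr$z[i]),
    direction = c(tr$dx[i], tr$dy[i], tr$dz[i]),
    magnitude_D = tr$mu_D[i], site_energy_cm1 = tr$E_cm1[i]))
  jsonlite::write_json(
    list(conformer = geom$conformer, ring_radius_nm = geom$ring_radius,
         dye_offset_nm = geom$dye_offset, transitions = recs),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_geometry_json
#' @export
read_geometry_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  rows <- lapply(obj$transitions, function(r)
    .td_row(r$site, r$role, r$label, unlist(r$origin), unlist(r$direction),
            r$magnitude_D, r$site_energy_cm1))
  rr <- obj$ring_radius_nm
  .assembly(do.call(rbind, rows), obj$conformer,
            if (is.null(rr)) NA_real_ else rr,
            if (is.null(obj$dye_offset_nm)) 0 else obj$dye_offset_nm)
}

#' Write an assembly as flat XYZ-style text
#'
#' One line per transition: `label x y z dx dy dz` (nm), for quick
#' visualization in external tools.
#'
#' @inheritParams write_geometry_json
#' @export
write_geometry_xyz <- function(geom, path) {
  stopifnot(inherits(geom, "assembly"))
  tr <- geom$transitions
  lines <- c(sprintf("%d", nrow(tr)),
             sprintf("conformer %s", geom$conformer),
             sprintf("%-16s %10.6f %10.6f %10.6f   %8.5f %8.5f %8.5f",
                     tr$label, tr$x, tr$y, tr$z, tr$dx, tr$dy, tr$dz))
  writeLines(lines, path)
  invisible(path)
}
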