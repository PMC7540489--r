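# The top-level fitted model object: configuration -> calibrated ring ->
# conformer geometries, Hamiltonians, spectra and transfer results, with the
# usual modelling-object methods.

#' Fit the light-harvesting exciton model
#'
#' Builds the complete exciton description of the dye-in-nanoring assembly
#' from a configuration: the six-site ring geometry, a least-squares
#' calibration of the ring parameters to the target absorption bands
#' (lowest band at 810 nm by default), the conformer-A and -B assemblies
#' with the axial dye, their Hamiltonians and exciton states, component and
#' complex absorption spectra with the additivity residual and dipole
#' redistribution, and the golden-rule transfer results for both conformers.
#'
#' The returned object supports [print()], [summary()], [coef()] (calibrated
#' parameters), [predict()] (absorbance on arbitrary wavelengths),
#' [plot()] (component spectra), [residuals()] (calibration residuals) and
#' [simulate()] (Monte-Carlo transfer-time distribution over the conformer
#' and disorder ensemble).
#'
#' @param config Configuration list, see [default_config()]; partial lists
#'   are completed and validated.
#' @param calibrate Run the ring calibration (default `TRUE`). With
#'   `FALSE` the configured parameters are used as-is.
#' @return An object of class `lh_model`.
#' @examples
#' m <- lh_model()
#' m
#' coef(m)
#' @export
lh_model <- function(config = default_config(), calibrate = TRUE) {
  cfg <- validate_config(config)
  lp <- lineshape_params(cfg$lineshape$shape, cfg$lineshape$fwhm_cm1,
                         as.numeric(unlist(cfg$lineshape$grid_nm)),
                         cfg$lineshape$grid_step_nm)
  sn <- cfg$environment$screening_n
  ring <- build_ring(cfg$geometry$n_sites, cfg$geometry$ring_radius_nm,
                     cfg$energies$site_energy_tangential_cm1,
                     cfg$energies$site_energy_axial_cm1,
                     cfg$dipoles$mu_tangential_D, cfg$dipoles$mu_axial_D)
  cal <- NULL
  if (calibrate) {
    tg <- cfg$calibration$targets
    targets <- data.frame(wavelength_nm = as.numeric(unlist(tg$wavelength_nm)))
    if (!is.null(tg$rel_intensity))
      targets$rel_intensity <- as.numeric(unlist(tg$rel_intensity))
    cal <- calibrate_ring(ring, targets,
                          free = as.character(unlist(cfg$calibration$free)),
                          lp = lp, screening_n = sn)
    ring <- cal$geometry
    emap <- c(site_energy_tangential = "site_energy_tangential_cm1",
              site_energy_axial = "site_energy_axial_cm1",
              dye_energy = "dye_energy_cm1")
    dmap <- c(mu_tangential = "mu_tangential_D", mu_axial = "mu_axial_D",
              mu_dye = "mu_dye_D")
    for (nm in names(cal$par)) {
      if (nm %in% names(emap)) cfg$energies[[emap[nm]]] <- unname(cal$par[nm])
      if (nm %in% names(dmap)) cfg$dipoles[[dmap[nm]]] <- unname(cal$par[nm])
    }
  }
  geomA <- add_dye(ring, "A", cfg$geometry$dye_offset_B_nm,
                   cfg$energies$dye_energy_cm1, cfg$dipoles$mu_dye_D)
  geomB <- add_dye(ring, "B", cfg$geometry$dye_offset_B_nm,
                   cfg$energies$dye_energy_cm1, cfg$dipoles$mu_dye_D)
  dye_only <- build_dye_only(cfg$energies$dye_energy_cm1,
                             cfg$dipoles$mu_dye_D)

  ring_states <- diagonalize(build_hamiltonian(ring, screening_n = sn))
  dye_states <- diagonalize(build_hamiltonian(dye_only, screening_n = sn))
  cplx_states <- diagonalize(build_hamiltonian(geomA, screening_n = sn))
  uncoupled_states <- diagonalize(
    build_hamiltonian(geomA, screening_n = sn, dye_coupling_scale = 0))

  spectra <- list(ring = broaden(stick_spectrum(ring_states), lp),
                  dye = broaden(stick_spectrum(dye_states), lp),
                  complex = broaden(stick_spectrum(cplx_states), lp))
  addres <- additivity_residual(spectra$complex, spectra$ring, spectra$dye)
  redis <- dipole_redistribution(cplx_states, uncoupled_states)

  st <- cfg$transfer$stokes_shift_cm1
  bt <- cfg$transfer$band_tol_cm1
  trA <- transfer_result(geomA, lp, stokes_shift_cm1 = st, band_tol = bt,
                         screening_n = sn)
  trB <- transfer_result(geomB, lp, stokes_shift_cm1 = st, band_tol = bt,
                         screening_n = sn)
  structure(list(config = cfg, lineshape = lp, calibration = cal,
                 geometry = list(ring = ring, A = geomA, B = geomB,
                                 dye = dye_only),
                 states = list(ring = ring_states, dye = dye_states,
                               complex = cplx_states),
                 spectra = spectra, additivity_residual = addres,
                 dipole_redistribution_D2 = redis,
                 transfer = list(A = trA, B = trB)),
            class = "lh_model")
}

#' Coupling of the dye to the lowest-energy ring band
#'
#' Convenience accessor: root-sum-square dye coupling (cm^-1) to the ring
#' exciton band at the longest wavelength (the 810 nm band of the calibrated
#' model), for the requested conformer.
#'
#' @param model An `lh_model`.
#' @param conformer `"A"` or `"B"`.
#' @return Coupling in cm^-1.
#' @export
lowest_band_coupling <- function(model, conformer = c("A", "B")) {
  stopifnot(inherits(model, "lh_model"))
  conformer <- match.arg(conformer)
  pb <- model$transfer[[conformer]]$per_band
  pb$V_cm1[which.max(pb$band_center_nm)]
}

#' @export
print.lh_model <- function(x, ...) {
  pbA <- x$transfer$A$per_band
  cat("Frenkel exciton model: axial dye in a porphyrin nanoring\n")
  cat(sprintf("  %d ring sites, radius %.3g nm; conformer-B dye offset %.3g nm\n",
              x$config$geometry$n_sites, x$config$geometry$ring_radius_nm,
              x$config$geometry$dye_offset_B_nm))
  if (!is.null(x$calibration))
    cat(sprintf("  calibrated ring bands at %s nm (rms residual %.3g)\n",
                paste(sprintf("%.1f", sort(x$calibration$fitted_peaks$wavelength_nm,
                                           decreasing = TRUE)),
                      collapse = ", "),
                x$calibration$residual))
  cat(sprintf("  dye-to-810 nm-band coupling: %.2f cm^-1\n",
              lowest_band_coupling(x, "A")))
  cat(sprintf("  transfer time: %.2f ps (A), %.2f ps (B)\n",
              x$transfer$A$transfer_time_ps, x$transfer$B$transfer_time_ps))
  cat(sprintf("  spectral additivity residual: %.2f%%\n",
              100 * x$additivity_residual))
  invisible(x)
}

#' @export
summary.lh_model <- function(object, ...) {
  s <- list(config = object$config,
            calibration_par = if (!is.null(object$calibration))
              object$calibration$par else NULL,
            calibration_residual = if (!is.null(object$calibration))
              object$calibration$residual else NULL,
            peaks = if (!is.null(object$calibration))
              object$calibration$fitted_peaks else NULL,
            coupling_profile_A = object$transfer$A$per_band,
            coupling_profile_B = object$transfer$B$per_band,
            transfer_time_A_ps = object$transfer$A$transfer_time_ps,
            transfer_time_B_ps = object$transfer$B$transfer_time_ps,
            additivity_residual = object$additivity_residual,
            dipole_redistribution_D2 = object$dipole_redistribution_D2)
  class(s) <- "summary.lh_model"
  s
}

#' @export
print.summary.lh_model <- function(x, ...) {
  cat("Frenkel exciton model of the dye-nanoring assembly\n\n")
  if (!is.null(x$calibration_par)) {
    cat("Calibrated parameters:\n")
    print(round(x$calibration_par, 4))
    cat(sprintf("rms calibration residual: %.4g\n\n", x$calibration_residual))
  }
  cat("Dye-band couplings and golden-rule rates (conformer A):\n")
  print.data.frame(format(as.data.frame(x$coupling_profile_A), digits = 4),
                   row.names = FALSE)
  cat("\nConformer B:\n")
  print.data.frame(format(as.data.frame(x$coupling_profile_B), digits = 4),
                   row.names = FALSE)
  cat(sprintf("\nTransfer times: %.3f ps (A), %.3f ps (B)\n",
              x$transfer_time_A_ps, x$transfer_time_B_ps))
  cat(sprintf("Additivity residual %.3f%%; dipole redistribution %+.3f D^2\n",
              100 * x$additivity_residual, x$dipole_redistribution_D2))
  invisible(x)
}

#' @export
coef.lh_model <- function(object, ...) {
  c(site_energy_tangential_cm1 = object$config$energies$site_energy_tangential_cm1,
    site_energy_axial_cm1 = object$config$energies$site_energy_axial_cm1,
    dye_energy_cm1 = object$config$energies$dye_energy_cm1,
    mu_tangential_D = object$config$dipoles$mu_tangential_D,
    mu_axial_D = object$config$dipoles$mu_axial_D,
    mu_dye_D = object$config$dipoles$mu_dye_D,
    screening_n = object$config$environment$screening_n)
}

#' @export
residuals.lh_model <- function(object, ...) {
  if (is.null(object$calibration)) return(numeric(0))
  object$calibration$residuals
}

#' Predict absorbance from a fitted exciton model
#'
#' Evaluates the broadened absorption spectrum of the chosen component on
#' arbitrary wavelengths (continuous evaluation, not grid interpolation).
#'
#' @param object An `lh_model`.
#' @param wavelengths Wavelengths in nm; defaults to the configured grid.
#' @param component `"complex"`, `"ring"`, `"dye"`, or `"sum"` (ring + dye).
#' @param ... Unused.
#' @return Data frame with `wavelength_nm` and `absorbance`.
#' @export
predict.lh_model <- function(object, wavelengths = NULL,
                             component = c("complex", "ring", "dye", "sum"),
                             ...) {
  component <- match.arg(component)
  if (is.null(wavelengths))
    wavelengths <- object$spectra$complex$wavelength_nm
  ab <- switch(component,
    complex = .eval_absorbance(wavelengths, object$spectra$complex$sticks,
                               object$lineshape),
    ring = .eval_absorbance(wavelengths, object$spectra$ring$sticks,
                            object$lineshape),
    dye = .eval_absorbance(wavelengths, object$spectra$dye$sticks,
                           object$lineshape),
    sum = .eval_absorbance(wavelengths, object$spectra$ring$sticks,
                           object$lineshape) +
      .eval_absorbance(wavelengths, object$spectra$dye$sticks,
                       object$lineshape))
  data.frame(wavelength_nm = wavelengths, absorbance = ab)
}

#' @export
plot.lh_model <- function(x, sticks = TRUE, ...) {
  lam <- x$spectra$complex$wavelength_nm
  comp <- x$spectra$complex$absorbance
  ringv <- x$spectra$ring$absorbance
  dyev <- x$spectra$dye$absorbance
  graphics::matplot(lam, cbind(comp, ringv, dyev, ringv + dyev), type = "l",
                    lty = c(1, 1, 1, 2), lwd = c(2, 1, 1, 1),
                    col = c("black", "red3", "purple3", "grey50"),
                    xlab = "wavelength (nm)", ylab = "absorbance (a.u.)",
                    ...)
  if (sticks) {
    sk <- x$spectra$complex$sticks
    sc <- max(comp) / max(sk$dipole_strength_D2)
    graphics::segments(sk$wavelength_nm, 0, sk$wavelength_nm,
                       sk$dipole_strength_D2 * sc, col = "grey70")
  }
  graphics::legend("topleft", bty = "n", lty = c(1, 1, 1, 2),
                   lwd = c(2, 1, 1, 1),
                   col = c("black", "red3", "purple3", "grey50"),
                   legend = c("complex", "ring", "dye", "ring + dye"))
  invisible(x)
}

#' Simulate the transfer-time distribution of a fitted model
#'
#' Draws `nsim` Monte-Carlo realizations of the conformer + static-disorder
#' ensemble and returns the golden-rule transfer-time distribution.
#'
#' @param object An `lh_model`.
#' @param nsim Number of realizations; defaults to the configured
#'   `disorder$n_realizations`.
#' @param seed RNG seed; defaults to the configured `disorder$seed`.
#' @param conformer `"both"` (Boltzmann-weighted A/B ensemble), `"A"`, or
#'   `"B"`.
#' @param ... Unused.
#' @return A `transfer_distribution`.
#' @examples
#' m <- lh_model()
#' d <- simulate(m, nsim = 200, seed = 7)
#' summary(d)
#' @export
simulate.lh_model <- function(object, nsim = NULL, seed = NULL,
                              conformer = c("both", "A", "B"), ...) {
  conformer <- match.arg(conformer)
  cfg <- object$config
  if (is.null(nsim)) nsim <- cfg$disorder$n_realizations
  if (is.null(seed)) seed <- cfg$disorder$seed
  if (is.null(seed))
    stop("invalid parameter: a seed is required (argument or config)")
  ens <- switch(conformer,
    both = conformer_ensemble(list(object$geometry$A, object$geometry$B),
                              delta_E = cfg$ensemble$delta_E_kJmol,
                              temperature = cfg$ensemble$temperature_K),
    A = conformer_ensemble(object$geometry$A),
    B = conformer_ensemble(object$geometry$B))
  dm <- disorder_model(cfg$disorder$sigma_cm1, nsim, seed = seed)
  transfer_distribution(ens, dm, lp = object$lineshape,
                        stokes_shift_cm1 = cfg$transfer$stokes_shift_cm1,
                        band_tol = cfg$transfer$band_tol_cm1,
                        screening_n = cfg$environment$screening_n)
}
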