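# Absorption spectra: stick spectra, lineshape broadening, ring calibration,
# spectral additivity and dipole redistribution.

#' Lineshape and wavelength-grid parameters
#'
#' @param shape `"gaussian"` or `"lorentzian"` (unit-area kernels on the
#'   energy axis).
#' @param fwhm Full width at half maximum in cm^-1 (default 350, a typical
#'   room-temperature porphyrin Q-band width).
#' @param grid_nm Length-2 ascending wavelength range in nm.
#' @param grid_step_nm Grid step in nm.
#' @return An object of class `lineshape_params`.
#' @examples
#' lineshape_params("gaussian", 350, c(600, 900), 0.25)
#' @export
lineshape_params <- function(shape = c("gaussian", "lorentzian"), fwhm = 350,
                             grid_nm = c(600, 900), grid_step_nm = 0.25) {
  shape <- match.arg(shape)
  if (!is.numeric(fwhm) || length(fwhm) != 1L || fwhm <= 0)
    stop("invalid parameter: 'fwhm' must be positive")
  if (!is.numeric(grid_nm) || length(grid_nm) != 2L || diff(grid_nm) <= 0)
    stop("invalid parameter: 'grid_nm' must be an ascending length-2 range")
  if (!is.numeric(grid_step_nm) || grid_step_nm <= 0)
    stop("invalid parameter: 'grid_step_nm' must be positive")
  structure(list(shape = shape, fwhm = fwhm, grid_nm = as.numeric(grid_nm),
                 grid_step_nm = grid_step_nm),
            class = "lineshape_params")
}

# Unit-area lineshape kernel on the energy axis, evaluated at detuning dE.
.line_kernel <- function(dE, fwhm, shape) {
  if (shape == "gaussian") {
    sg <- fwhm / (2 * sqrt(2 * log(2)))
    stats::dnorm(dE, 0, sg)
  } else {
    hw <- fwhm / 2
    (hw / pi) / (dE^2 + hw^2)
  }
}

#' Stick spectrum of a set of exciton states
#'
#' One stick per eigenstate at `lambda = 10^7 / E`, weighted by the state's
#' dipole strength. Dark states (strength below 1e-12 D^2) are kept with
#' zero weight so that state counting is preserved.
#'
#' @param states An `exciton_states` object.
#' @return Data frame with columns `wavelength_nm`, `dipole_strength_D2`.
#' @examples
#' dye <- build_dye_only(12500, 11)
#' stick_spectrum(diagonalize(build_hamiltonian(dye)))  # one stick at 800 nm
#' @export
stick_spectrum <- function(states) {
  stopifnot(inherits(states, "exciton_states"))
  w <- states$dipole_strengths
  w[w < 1e-12] <- 0
  data.frame(wavelength_nm = cm1_to_nm(states$energies),
             dipole_strength_D2 = w)
}

# Continuous absorbance A(lambda) for a stick list: sum over sticks of
# weight * E_stick * kernel(E - E_stick), evaluated via the energy axis.
.eval_absorbance <- function(lambda_nm, sticks, lp) {
  E <- nm_to_cm1(lambda_nm)
  A <- numeric(length(E))
  for (s in seq_len(nrow(sticks))) {
    w <- sticks$dipole_strength_D2[s]
    if (w == 0) next
    Es <- nm_to_cm1(sticks$wavelength_nm[s])
    A <- A + w * Es * .line_kernel(E - Es, lp$fwhm, lp$shape)
  }
  A
}

#' Broaden a stick spectrum
#'
#' Convolves the sticks with unit-area lineshape kernels on the energy axis,
#' scaling each kernel by the stick's dipole strength times its transition
#' energy (absorbance convention `A ~ E |mu|^2`), and evaluates the result on
#' the wavelength grid.
#'
#' @param sticks Data frame from [stick_spectrum()] (columns `wavelength_nm`,
#'   `dipole_strength_D2`).
#' @param lp A [lineshape_params()] object.
#' @return An object of class `exciton_spectrum`: list with `wavelength_nm`,
#'   `absorbance` (arbitrary units) and the input `sticks` flagged with an
#'   `in_grid` column.
#' @export
broaden <- function(sticks, lp) {
  stopifnot(is.data.frame(sticks), inherits(lp, "lineshape_params"))
  grid <- seq(lp$grid_nm[1], lp$grid_nm[2], by = lp$grid_step_nm)
  sticks$in_grid <- sticks$wavelength_nm >= lp$grid_nm[1] &
    sticks$wavelength_nm <= lp$grid_nm[2]
  live <- sticks$dipole_strength_D2 > 0
  if (any(live) && !any(sticks$in_grid[live]))
    warning("empty spectrum: no (bright) stick lies inside the wavelength grid")
  structure(list(wavelength_nm = grid,
                 absorbance = .eval_absorbance(grid, sticks, lp),
                 sticks = sticks, lineshape = lp),
            class = "exciton_spectrum")
}

#' @export
print.exciton_spectrum <- function(x, ...) {
  imax <- which.max(x$absorbance)
  cat(sprintf(
    "<spectrum> %d points, %.0f-%.0f nm; %d stick(s); max at %.1f nm\n",
    length(x$wavelength_nm), min(x$wavelength_nm), max(x$wavelength_nm),
    nrow(x$sticks), x$wavelength_nm[imax]))
  invisible(x)
}

#' @export
plot.exciton_spectrum <- function(x, sticks = TRUE, ...) {
  graphics::plot(x$wavelength_nm, x$absorbance, type = "l",
                 xlab = "wavelength (nm)", ylab = "absorbance (a.u.)", ...)
  if (sticks && nrow(x$sticks)) {
    sc <- max(x$absorbance) / max(x$sticks$dipole_strength_D2, 1e-12)
    graphics::segments(x$sticks$wavelength_nm, 0, x$sticks$wavelength_nm,
                       x$sticks$dipole_strength_D2 * sc, col = "grey50")
  }
  invisible(x)
}

# Locate the local maxima of the continuous absorbance near each target.
# Maxima are found on the evaluation grid and refined by a golden-section
# search on the continuous function, so positions vary smoothly with the
# model parameters (important for derivative-based calibration).
.find_peaks <- function(sticks, lp) {
  grid <- seq(lp$grid_nm[1], lp$grid_nm[2], by = lp$grid_step_nm)
  A <- .eval_absorbance(grid, sticks, lp)
  n <- length(A)
  cand <- which(A[2:(n - 1)] > A[1:(n - 2)] & A[2:(n - 1)] >= A[3:n]) + 1L
  if (!length(cand)) return(data.frame(wavelength_nm = numeric(0),
                                       height = numeric(0)))
  peaks <- vapply(cand, function(i) {
    stats::optimize(function(l) .eval_absorbance(l, sticks, lp),
                    lower = grid[i - 1L], upper = grid[i + 1L],
                    maximum = TRUE, tol = 1e-8)$maximum
  }, numeric(1))
  data.frame(wavelength_nm = peaks,
             height = .eval_absorbance(peaks, sticks, lp))
}

# Apply named free parameters to an assembly's transitions (by label).
.apply_ring_params <- function(geom, par) {
  tr <- geom$transitions
  map <- list(site_energy_tangential = c("ring-tangential", "E_cm1"),
              site_energy_axial = c("ring-axial", "E_cm1"),
              mu_tangential = c("ring-tangential", "mu_D"),
              mu_axial = c("ring-axial", "mu_D"),
              dye_energy = c("dye", "E_cm1"),
              mu_dye = c("dye", "mu_D"))
  for (nm in names(par)) {
    if (is.null(map[[nm]]))
      stop("invalid parameter: unknown free parameter '", nm, "'")
    tr[tr$label == map[[nm]][1], map[[nm]][2]] <- par[[nm]]
  }
  geom$transitions <- tr
  geom
}

# Current values of the named parameters for an assembly.
.extract_ring_params <- function(geom, free) {
  tr <- geom$transitions
  map <- list(site_energy_tangential = c("ring-tangential", "E_cm1"),
              site_energy_axial = c("ring-axial", "E_cm1"),
              mu_tangential = c("ring-tangential", "mu_D"),
              mu_axial = c("ring-axial", "mu_D"),
              dye_energy = c("dye", "E_cm1"),
              mu_dye = c("dye", "mu_D"))
  vapply(free, function(nm) {
    if (is.null(map[[nm]]))
      stop("invalid parameter: unknown free parameter '", nm, "'")
    v <- tr[tr$label == map[[nm]][1], map[[nm]][2]]
    if (!length(v)) stop("invalid parameter: assembly lacks '", nm, "' label")
    v[1]
  }, numeric(1))
}

#' Calibrate ring parameters to target absorption bands
#'
#' Bounded least-squares fit of the chosen free parameters (site energies
#' and/or dipole magnitudes) so that the broadened spectrum of the assembly
#' has local maxima at the target wavelengths, optionally with prescribed
#' relative intensities. Each target is matched to the nearest local maximum
#' of the model spectrum; position residuals are in nm and intensity
#' residuals (peak heights normalised to the largest matched peak) are
#' weighted by `intensity_weight` nm per unit. The optimizer (L-BFGS-B)
#' starts from the assembly's current values, so the fit is deterministic
#' and idempotent: re-running on its own output leaves the parameters
#' unchanged.
#'
#' @param geom Assembly to calibrate (normally `ring_only`).
#' @param targets Data frame with columns `wavelength_nm` and optionally
#'   `rel_intensity` (`NA` entries ignored). At least one band required.
#' @param free Character vector of free parameters among
#'   `site_energy_tangential`, `site_energy_axial`, `mu_tangential`,
#'   `mu_axial`, `dye_energy`, `mu_dye`.
#' @param lp [lineshape_params()] used for the broadened spectrum.
#' @param screening_n Medium refractive index.
#' @param intensity_weight Conversion of relative-intensity residuals to the
#'   nm scale of the position residuals (default 100).
#' @param control Passed to [stats::optim()] (method `L-BFGS-B`).
#' @return List with `geometry` (calibrated assembly), `par` (fitted values),
#'   `residual` (root-mean-square residual), `fitted_peaks` (data frame) and
#'   `convergence` (0 for success).
#' @examples
#' dye <- build_dye_only(13000, 5)
#' cal <- calibrate_ring(dye, data.frame(wavelength_nm = 790),
#'                       free = "dye_energy", lp = lineshape_params())
#' cal$par  # 10^7 / 790
#' @export
calibrate_ring <- function(geom, targets,
                           free = c("site_energy_tangential",
                                    "site_energy_axial"),
                           lp = lineshape_params(), screening_n = 1.424,
                           intensity_weight = 100, control = list()) {
  stopifnot(inherits(geom, "assembly"), is.data.frame(targets),
            "wavelength_nm" %in% names(targets), nrow(targets) >= 1L)
  if (!"rel_intensity" %in% names(targets))
    targets$rel_intensity <- NA_real_
  free <- unique(free)
  p0 <- .extract_ring_params(geom, free)

  resid_vec <- function(p) {
    names(p) <- free
    g <- .apply_ring_params(geom, as.list(p))
    st <- diagonalize(build_hamiltonian(g, screening_n = screening_n))
    pk <- .find_peaks(stick_spectrum(st), lp)
    if (!nrow(pk)) return(rep(1e3, nrow(targets)))
    idx <- vapply(targets$wavelength_nm,
                  function(l) which.min(abs(pk$wavelength_nm - l)), 1L)
    res <- pk$wavelength_nm[idx] - targets$wavelength_nm
    hi <- targets$rel_intensity
    if (any(!is.na(hi))) {
      rel <- pk$height[idx] / max(pk$height[idx])
      res <- c(res, intensity_weight *
                 (rel[!is.na(hi)] - hi[!is.na(hi)] / max(hi, na.rm = TRUE)))
    }
    res
  }
  obj <- function(p) sum(resid_vec(p)^2)

  lower <- ifelse(grepl("^mu", free), 0.05, 8000)
  upper <- ifelse(grepl("^mu", free), 30, 18000)
  ctrl <- utils::modifyList(
    list(parscale = ifelse(grepl("^mu", free), 0.1, 50),
         ndeps = rep(1e-7, length(free)), factr = 1e4, maxit = 500),
    control)
  fit <- stats::optim(p0, obj, method = "L-BFGS-B", lower = lower,
                      upper = upper, control = ctrl)
  if (fit$convergence != 0)
    stop(sprintf(
      "calibration failure: optimizer did not converge (code %d, residual %g)",
      fit$convergence, sqrt(fit$value / nrow(targets))))
  names(fit$par) <- free
  g <- .apply_ring_params(geom, as.list(fit$par))
  st <- diagonalize(build_hamiltonian(g, screening_n = screening_n))
  pk <- .find_peaks(stick_spectrum(st), lp)
  list(geometry = g, par = fit$par,
       residual = sqrt(fit$value / nrow(targets)),
       residuals = resid_vec(fit$par),
       fitted_peaks = pk, targets = targets, convergence = fit$convergence)
}

#' Additivity residual of the complex spectrum
#'
#' Relative integrated absolute deviation of the complex spectrum from the
#' sum of its component spectra:
#' `integral |A_complex - (A_ring + A_dye)| / integral (A_ring + A_dye)`
#' (trapezoid on the common wavelength grid). Zero when the dye-ring
#' coupling vanishes (block-diagonal Hamiltonian); small but nonzero for the
#' coupled complex, quantifying how subtle the coherent-coupling signature
#' is in absorption.
#'
#' @param spec_complex,spec_ring,spec_dye `exciton_spectrum` objects on one
#'   common grid.
#' @return Dimensionless relative residual.
#' @export
additivity_residual <- function(spec_complex, spec_ring, spec_dye) {
  for (s in list(spec_complex, spec_ring, spec_dye))
    stopifnot(inherits(s, "exciton_spectrum"))
  if (!isTRUE(all.equal(spec_complex$wavelength_nm, spec_ring$wavelength_nm)) ||
      !isTRUE(all.equal(spec_complex$wavelength_nm, spec_dye$wavelength_nm)))
    stop("grid mismatch: spectra must share one wavelength grid")
  lam <- spec_complex$wavelength_nm
  trap <- function(y) sum(diff(lam) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  ref <- spec_ring$absorbance + spec_dye$absorbance
  trap(abs(spec_complex$absorbance - ref)) / trap(ref)
}

#' Dipole redistribution towards the dye
#'
#' Measures the coherent-coupling-induced transfer of absorption strength
#' into dye-dominated exciton states: states whose squared dye coefficient
#' exceeds 0.5 are classed as dye states, and the difference of their summed
#' dipole strengths between the coupled and uncoupled models is returned
#' (positive = dye gains strength, here at the expense of the nearby ring
#' band).
#'
#' @param states_coupled,states_uncoupled `exciton_states` on the same basis
#'   dimension (typically from [build_hamiltonian()] with
#'   `dye_coupling_scale` 1 and 0).
#' @param dye_index Basis row of the dye transition; found from the basis
#'   `role` column when omitted.
#' @return Signed dipole strength moved to the dye states (Debye^2).
#' @export
dipole_redistribution <- function(states_coupled, states_uncoupled,
                                  dye_index = NULL) {
  stopifnot(inherits(states_coupled, "exciton_states"),
            inherits(states_uncoupled, "exciton_states"))
  n <- length(states_coupled$energies)
  if (n != length(states_uncoupled$energies))
    stop("invalid parameter: state sets differ in basis dimension")
  if (is.null(dye_index)) {
    dye_index <- which(states_coupled$basis$role == "dye")
    if (length(dye_index) != 1L)
      stop("missing dye: supply 'dye_index' or a basis with one dye row")
  }
  dye_sum <- function(st) {
    w <- st$coefficients[dye_index, ]^2 > 0.5
    sum(st$dipole_strengths[w])
  }
  dye_sum(states_coupled) - dye_sum(states_uncoupled)
}
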