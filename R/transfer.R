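# Golden-rule (second-order perturbation theory) dye-to-ring energy transfer:
# spectral overlaps, per-band rates, and transfer-time distributions over
# conformer and static-disorder ensembles.

#' Spectral line descriptor
#'
#' A unit-area lineshape on the energy axis, used for donor emission and
#' acceptor band profiles in the overlap integral.
#'
#' @param center Line centre in cm^-1.
#' @param fwhm Full width at half maximum in cm^-1.
#' @param shape `"gaussian"` or `"lorentzian"`.
#' @return An object of class `spectral_line`.
#' @export
spectral_line <- function(center, fwhm, shape = c("gaussian", "lorentzian")) {
  shape <- match.arg(shape)
  if (!is.numeric(center) || length(center) != 1L || center <= 0)
    stop("invalid parameter: 'center' must be a positive energy in cm^-1")
  if (!is.numeric(fwhm) || length(fwhm) != 1L || fwhm <= 0)
    stop("invalid parameter: 'fwhm' must be positive")
  structure(list(center = center, fwhm = fwhm, shape = shape),
            class = "spectral_line")
}

#' Donor-acceptor spectral overlap
#'
#' Overlap integral `J = integral L_donor(E) L_acceptor(E) dE` of two
#' unit-area lineshapes (per cm^-1). Gaussian-Gaussian and
#' Lorentzian-Lorentzian pairs use the closed-form convolution values
#' (a normal density with summed variances, respectively a Lorentzian with
#' summed half-widths, evaluated at the centre detuning); mixed pairs are
#' integrated numerically.
#'
#' @param donor,acceptor [spectral_line()] objects.
#' @return Overlap in (cm^-1)^-1; maximal at zero detuning and decaying to 0
#'   for separations much larger than the widths.
#' @examples
#' f <- 350
#' d <- spectral_line(12500, f); a <- spectral_line(12500, f)
#' spectral_overlap(d, a)  # = sqrt(2*log(2)/pi)/f = 0.66428/f
#' @export
spectral_overlap <- function(donor, acceptor) {
  stopifnot(inherits(donor, "spectral_line"),
            inherits(acceptor, "spectral_line"))
  dE <- donor$center - acceptor$center
  if (donor$shape == "gaussian" && acceptor$shape == "gaussian") {
    s2 <- (donor$fwhm^2 + acceptor$fwhm^2) / (8 * log(2))
    stats::dnorm(dE, 0, sqrt(s2))
  } else if (donor$shape == "lorentzian" && acceptor$shape == "lorentzian") {
    hw <- (donor$fwhm + acceptor$fwhm) / 2
    (hw / pi) / (dE^2 + hw^2)
  } else {
    f <- function(E) .line_kernel(E - donor$center, donor$fwhm, donor$shape) *
      .line_kernel(E - acceptor$center, acceptor$fwhm, acceptor$shape)
    # finite window: far Lorentzian tails contribute negligibly to the product
    wide <- 200 * max(donor$fwhm, acceptor$fwhm)
    lo <- min(donor$center, acceptor$center) - wide
    hi <- max(donor$center, acceptor$center) + wide
    stats::integrate(f, lo, hi, rel.tol = 1e-9, subdivisions = 500L)$value
  }
}

#' Golden-rule transfer rate
#'
#' Second-order perturbation theory (Fermi golden rule) rate for a coupling
#' `V` (cm^-1) and donor-acceptor spectral overlap `J` (per cm^-1):
#' `k = 2 pi V^2 J / hbar` with `hbar = 1/(2 pi c) = 5.3088` cm^-1 ps
#' (`c` the speed of light in cm/ps), i.e. `k = 4 pi^2 c V^2 J` in ps^-1.
#' Quadratic in the coupling and linear in the overlap; agrees with the
#' exact decay dynamics of a level coupled to a dense manifold in the
#' weak-coupling (Weisskopf-Wigner) regime.
#'
#' @param V_cm1 Electronic coupling in cm^-1 (>= 0).
#' @param overlap_J Spectral overlap in (cm^-1)^-1 (>= 0).
#' @return Rate in ps^-1.
#' @examples
#' golden_rule_rate(25, 1.9e-3)  # ~1.4 ps^-1
#' @export
golden_rule_rate <- function(V_cm1, overlap_J) {
  if (any(V_cm1 < 0) || any(overlap_J < 0))
    stop("invalid parameter: coupling and overlap must be non-negative")
  4 * pi^2 * .c_cm_ps * V_cm1^2 * overlap_J
}

# Fill the k_ps_inv column of a coupling profile for a given donor line.
.fill_rates <- function(profile, donor_center, lp) {
  donor <- spectral_line(donor_center, lp$fwhm, lp$shape)
  profile$k_ps_inv <- vapply(seq_len(nrow(profile)), function(b) {
    acc <- spectral_line(nm_to_cm1(profile$band_center_nm[b]), lp$fwhm,
                         lp$shape)
    golden_rule_rate(profile$V_cm1[b], spectral_overlap(donor, acc))
  }, numeric(1))
  profile
}

#' Dye-to-ring transfer rates for one assembly
#'
#' Full second-order-perturbation-theory pipeline for a single (disorder
#' realization of an) assembly: exciton couplings between the dye and each
#' ring band, spectral overlap of the dye emission line with each band, and
#' the golden-rule rate per band. The donor emission line is the dye
#' absorption lineshape red-shifted by the Stokes shift.
#'
#' @param geom Assembly containing exactly one dye transition.
#' @param lp [lineshape_params()] giving the common lineshape width/shape.
#' @param stokes_shift_cm1 Dye Stokes shift in cm^-1. Default from the
#'   observed 725 nm excitation / 798 nm emission pair of the free dye
#'   rotaxane (about 1262 cm^-1).
#' @param band_tol Band grouping tolerance in cm^-1 (see
#'   [dye_band_couplings()]).
#' @param screening_n Medium refractive index.
#' @param dye_coupling_scale Scale factor on the dye-ring coupling block
#'   (see [build_hamiltonian()]).
#' @return An object of class `transfer_result`: `per_band`
#'   (a `coupling_profile` with rates filled), `total_rate_ps_inv`,
#'   `transfer_time_ps` (`Inf`, flagged via `zero_rate`, when all couplings
#'   vanish) and `donor_center_cm1`.
#' @export
transfer_result <- function(geom, lp = lineshape_params(),
                            stokes_shift_cm1 = nm_to_cm1(725) - nm_to_cm1(798),
                            band_tol = 50, screening_n = 1.424,
                            dye_coupling_scale = 1) {
  stopifnot(inherits(geom, "assembly"))
  dye_rows <- which(geom$transitions$role == "dye")
  if (length(dye_rows) != 1L)
    stop("missing dye: 'geom' must contain exactly one dye transition")
  Hfull <- build_hamiltonian(geom, screening_n = screening_n,
                             dye_coupling_scale = dye_coupling_scale)
  ring_states <- diagonalize(build_hamiltonian(remove_dye(geom),
                                               screening_n = screening_n))
  profile <- dye_band_couplings(Hfull, ring_states, band_tol = band_tol)
  donor_center <- geom$transitions$E_cm1[dye_rows] - stokes_shift_cm1
  profile <- .fill_rates(profile, donor_center, lp)
  total <- sum(profile$k_ps_inv)
  structure(list(per_band = profile, total_rate_ps_inv = total,
                 transfer_time_ps = if (total > 0) 1 / total else Inf,
                 zero_rate = total == 0, donor_center_cm1 = donor_center),
            class = "transfer_result")
}

#' @export
print.transfer_result <- function(x, ...) {
  cat("<transfer result>\n")
  print.data.frame(format(as.data.frame(x$per_band), digits = 4),
                   row.names = FALSE)
  if (x$zero_rate) {
    cat("  total rate 0: dye decoupled, no energy transfer (time = Inf)\n")
  } else {
    cat(sprintf("  total rate %.4f ps^-1, transfer time %.3f ps\n",
                x$total_rate_ps_inv, x$transfer_time_ps))
  }
  invisible(x)
}

# Shared fast path: rates for one Hamiltonian realization. `pre` carries the
# precomputed index bookkeeping; `Hm` is the full matrix with the realized
# diagonal. Must stay numerically identical to transfer_result().
.rates_from_matrix <- function(Hm, pre, stokes_shift_cm1, lp, band_tol) {
  Hr <- Hm[pre$ring, pre$ring, drop = FALSE]
  ev <- eigen(Hr, symmetric = TRUE)
  ord <- order(ev$values)
  energies <- ev$values[ord]
  Vk <- as.numeric(crossprod(ev$vectors[, ord, drop = FALSE],
                             Hm[pre$dye, pre$ring]))
  bands <- .group_bands(energies, band_tol)
  donor <- spectral_line(Hm[pre$dye, pre$dye] - stokes_shift_cm1, lp$fwhm,
                         lp$shape)
  ktot <- 0
  for (idx in bands) {
    v2 <- sum(Vk[idx]^2)
    if (v2 <= 0) next
    center <- sum(Vk[idx]^2 * energies[idx]) / v2
    ktot <- ktot + golden_rule_rate(
      sqrt(v2), spectral_overlap(donor, spectral_line(center, lp$fwhm,
                                                      lp$shape)))
  }
  ktot
}

#' Transfer-time distribution over a conformer + disorder ensemble
#'
#' Monte-Carlo sampling of the golden-rule transfer time: each realization
#' draws a conformer by its Boltzmann weight and an independent Gaussian
#' static-disorder shift for every transition energy, then evaluates the
#' total dye-to-ring rate exactly as [transfer_result()] does. Reproducible
#' under a fixed seed; the caller's RNG stream is left untouched.
#'
#' @param ens A [conformer_ensemble()] whose members all contain a dye.
#' @param dm A [disorder_model()].
#' @inheritParams transfer_result
#' @param n_boot Bootstrap replicates for the 95% percentile confidence
#'   intervals of the summary statistics (default 500).
#' @return An object of class `transfer_distribution`: `samples_ps`,
#'   `conformer` (per-sample label), `median_ps`, `mean_rate_ps_inv`
#'   (ensemble mean of the rate), `p_within_50ps`, bootstrap `ci` list,
#'   `n_samples` and `seed`. Use [prob_within()] for arbitrary thresholds.
#' @export
transfer_distribution <- function(ens, dm, lp = lineshape_params(),
                                  stokes_shift_cm1 =
                                    nm_to_cm1(725) - nm_to_cm1(798),
                                  band_tol = 50, screening_n = 1.424,
                                  n_boot = 500) {
  stopifnot(inherits(ens, "conformer_ensemble"),
            inherits(dm, "disorder_model"))
  pre <- lapply(ens$members, function(g) {
    dye <- which(g$transitions$role == "dye")
    if (length(dye) != 1L)
      stop("missing dye: every ensemble member needs exactly one dye")
    H <- build_hamiltonian(g, screening_n = screening_n)
    list(H0 = H$matrix, diag0 = diag(H$matrix), dye = dye,
         ring = which(g$transitions$role != "dye"))
  })
  ktr <- nrow(ens$members[[1]]$transitions)
  if (!all(vapply(ens$members, function(g) nrow(g$transitions), 1L) == ktr))
    stop("invalid parameter: ensemble members differ in basis size")
  n <- dm$n_realizations
  res <- .with_seed(dm$seed, {
    conf <- if (length(ens$members) == 1L) rep(1L, n)
            else findInterval(stats::runif(n),
                              cumsum(ens$weights)[-length(ens$weights)]) + 1L
    shifts <- .disorder_shifts(dm, ktr)
    rates <- numeric(n)
    for (i in seq_len(n)) {
      p <- pre[[conf[i]]]
      Hm <- p$H0
      diag(Hm) <- p$diag0 + shifts[i, ]
      rates[i] <- .rates_from_matrix(Hm, p, stokes_shift_cm1, lp, band_tol)
    }
    times <- ifelse(rates > 0, 1 / rates, Inf)
    ci <- NULL
    if (n_boot > 0 && n > 1) {
      bm <- matrix(sample.int(n, n * n_boot, replace = TRUE), ncol = n_boot)
      med <- apply(bm, 2, function(j) stats::median(times[j]))
      mrt <- apply(bm, 2, function(j) mean(rates[j]))
      ci <- list(median_ps = stats::quantile(med, c(0.025, 0.975),
                                             names = FALSE),
                 mean_rate_ps_inv = stats::quantile(mrt, c(0.025, 0.975),
                                                    names = FALSE))
    }
    list(times = times, rates = rates, conf = conf, ci = ci)
  })
  conf_lab <- vapply(ens$members, function(g) g$conformer, "")
  structure(list(samples_ps = res$times, rates_ps_inv = res$rates,
                 conformer = conf_lab[res$conf],
                 median_ps = stats::median(res$times),
                 mean_rate_ps_inv = mean(res$rates),
                 p_within_50ps = mean(res$times < 50),
                 ci = res$ci, n_samples = n, seed = dm$seed,
                 sigma_site = dm$sigma_site),
            class = "transfer_distribution")
}

#' Probability that transfer completes within a time threshold
#'
#' Empirical CDF of the sampled transfer times, evaluated at `T_ps`;
#' monotone non-decreasing in the threshold with limit 1.
#'
#' @param dist A `transfer_distribution`.
#' @param T_ps Threshold(s) in ps.
#' @return Fraction of samples with transfer time strictly below `T_ps`.
#' @export
prob_within <- function(dist, T_ps) {
  stopifnot(inherits(dist, "transfer_distribution"), is.numeric(T_ps))
  vapply(T_ps, function(T) mean(dist$samples_ps < T), numeric(1))
}

#' @export
print.transfer_distribution <- function(x, ...) {
  cat(sprintf(
    "<transfer-time distribution> n = %d (seed %d, sigma = %g cm^-1)\n",
    x$n_samples, x$seed, x$sigma_site))
  cat(sprintf("  median %.3f ps, mean rate %.4f ps^-1 (1/%.3f ps)\n",
              x$median_ps, x$mean_rate_ps_inv, 1 / x$mean_rate_ps_inv))
  cat(sprintf("  P(t < 50 ps) = %.4f\n", x$p_within_50ps))
  invisible(x)
}

#' @export
summary.transfer_distribution <- function(object, ...) {
  s <- list(n = object$n_samples, seed = object$seed,
            median_ps = object$median_ps,
            mean_rate_ps_inv = object$mean_rate_ps_inv,
            inv_mean_rate_ps = 1 / object$mean_rate_ps_inv,
            p_within_50ps = object$p_within_50ps,
            quantiles_ps = stats::quantile(object$samples_ps,
                                           c(0.05, 0.25, 0.5, 0.75, 0.95)),
            by_conformer = tapply(object$samples_ps, object$conformer,
                                  stats::median),
            ci = object$ci)
  class(s) <- "summary.transfer_distribution"
  s
}

#' @export
print.summary.transfer_distribution <- function(x, ...) {
  cat(sprintf("Transfer-time distribution (n = %d, seed %d)\n", x$n, x$seed))
  cat(sprintf("  median        %.3f ps", x$median_ps))
  if (!is.null(x$ci))
    cat(sprintf("   [95%% CI %.3f, %.3f]", x$ci$median_ps[1],
                x$ci$median_ps[2]))
  cat("\n")
  cat(sprintf("  mean rate     %.4f ps^-1 (1/%.3f ps)", x$mean_rate_ps_inv,
              x$inv_mean_rate_ps))
  if (!is.null(x$ci))
    cat(sprintf("   [95%% CI %.4f, %.4f]", x$ci$mean_rate_ps_inv[1],
                x$ci$mean_rate_ps_inv[2]))
  cat("\n")
  cat(sprintf("  P(t < 50 ps)  %.4f\n", x$p_within_50ps))
  cat("  quantiles (ps):\n")
  print(round(x$quantiles_ps, 3))
  if (length(x$by_conformer) > 1) {
    cat("  median by conformer (ps):\n")
    print(round(x$by_conformer, 3))
  }
  invisible(x)
}

#' @export
plot.transfer_distribution <- function(x, breaks = 50, ...) {
  graphics::hist(x$samples_ps[is.finite(x$samples_ps)], breaks = breaks,
                 xlab = "transfer time (ps)", main = "", ...)
  graphics::abline(v = x$median_ps, lty = 2)
  invisible(x)
}
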