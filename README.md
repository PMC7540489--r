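# excitonring

A Frenkel exciton model of an artificial light-harvesting complex: a
near-infrared cyanine dye (Cy7-type) held by a cyclodextrin rotaxane on the
axis of a six-porphyrin zinc nanoring — a synthetic mimic of the bacterial
LH1 antenna ring around its reaction centre. The package is for
photophysicists and modellers who want a small, fully reproducible pipeline
from molecular geometry to absorption spectra, dye–ring couplings,
golden-rule energy-transfer kinetics, and the inversion of
fluorescence-quenching data into transfer-time estimates.

## The model in brief

Each porphyrin contributes two orthogonal Q-type point transition dipoles
(tangential and axial); the dye is a single axial dipole on the ring axis,
either centred in the zinc plane (conformer A) or shifted 0.4 nm towards
one rim (conformer B). The Frenkel Hamiltonian uses point-dipole couplings

    H_ij = C κ_ij μ_i μ_j / (n² R_ij³),
    κ_ij = μ̂_i·μ̂_j − 3 (μ̂_i·R̂_ij)(μ̂_j·R̂_ij),

with C = 5.0341 cm⁻¹ D⁻² nm³ and n = 1.424 (CH₂Cl₂). Ring site energies
and effective dipole magnitudes are calibrated so the broadened ring
spectrum peaks at 810 nm (axial manifold) and 760 nm (tangential
manifold). By the ring's six-fold symmetry the axial dye couples **only**
to the axial manifold, with root-sum-square band coupling
V = √6 · C μ_dye μ_axial / (n² r³) ≈ 20.5 cm⁻¹ to the 810 nm band.

Dye→ring transfer is second-order perturbation theory (Fermi golden rule),

    k_b = (2π/ħ) V_b² J_b,   ħ = 1/(2πc) = 5.3088 cm⁻¹ ps,

with J_b the overlap of the Stokes-shifted dye emission line (798 nm) with
the acceptor band lineshape (Gaussian, FWHM 350 cm⁻¹). Transfer-time
distributions are Monte-Carlo ensembles over the Boltzmann-weighted A/B
conformers (ΔE = 0.7 kJ/mol, 298 K) and Gaussian static site-energy
disorder (σ = 50 cm⁻¹). Independently, the measured brightness ratio
r = 0.0051 and donor lifetime τ = 0.97 ns invert through the rate
competition τ_ET = r·τ/(1−r) ≈ 5 ps.

## Worked example

```r
library(excitonring)
m <- lh_model()          # build + calibrate the default model
m
#> Frenkel exciton model: axial dye in a porphyrin nanoring
#>   6 ring sites, radius 1.2 nm; conformer-B dye offset 0.4 nm
#>   calibrated ring bands at 810.0, 760.0 nm (rms residual 2.29e-07)
#>   dye-to-810 nm-band coupling: 20.52 cm^-1
#>   transfer time: 1.56 ps (A), 4.37 ps (B)
#>   spectral additivity residual: 0.66%
```

The calibrated coupling (20.5 cm⁻¹) quantifies a coherent dye–ring
interaction far too small to shift the absorption spectrum visibly — the
complex absorbs almost additively (residual 0.7%) — yet fast enough to
drain the dye in picoseconds. The ensemble over conformers and disorder:

```r
summary(simulate(m, nsim = 2000, seed = 1))
#> Transfer-time distribution (n = 2000, seed 1)
#>   median        2.007 ps   [95% CI 1.921, 2.140]
#>   mean rate     0.4711 ps^-1 (1/2.123 ps)   [95% CI 0.4620, 0.4811]
#>   P(t < 50 ps)  1.0000
#>   median by conformer (ps):
#>     A     B
#> 1.524 4.398
```

Conformer A transfers in ~1.5 ps, the rim-shifted conformer B in ~4.4 ps;
every realization completes within 50 ps. The purely experimental
inversion agrees:

```r
print(kinetic_scheme())   # brightness ratio 0.0051, lifetime 0.97 ns
#>   => k_ET = 0.2011 ps^-1, transfer time 4.97 ps, quenching 99.49%
```

`plot(m)` overlays the complex, ring, dye and ring+dye spectra with the
stick spectrum; `run_pipeline(default_config(seed = 1), outdir = "results")`
writes the spectra, coupling profile, transfer samples and quenching report
as CSV/JSON together with a reproducibility manifest. A thin command-line
wrapper with the same stages lives in `inst/cli/lhring.R`.

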