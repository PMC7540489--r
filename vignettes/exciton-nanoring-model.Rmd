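---
title: "A Frenkel exciton model of an axial dye in a porphyrin nanoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Frenkel exciton model of an axial dye in a porphyrin nanoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
```

```{r setup}
library(excitonring)
```

## The system and the question

A near-infrared cyanine dye (a Cy7-type hexamethylindotricarbocyanine)
threaded through a cyclodextrin rotaxane is held on the axis of a cyclic
array of six zinc porphyrins — a synthetic analogue of the bacterial LH1
antenna ring surrounding its reaction centre. Photophysically the assembly
behaves as an almost ideal funnel: although the absorption spectrum of the
complex is nearly the sum of its parts, the dye's emission is quenched by
more than 99%, implying sub-10-ps energy transfer from the central dye to
the surrounding ring.

This package asks the quantitative question behind that observation: how
large must the coherent dye–ring coupling be, and what transfer-time
distribution does it produce, once the ring's exciton structure, the two
molecular conformers and static energetic disorder are taken into account?

## The model

Every optical transition is a point transition dipole with a position
$\mathbf{r}_i$ (nm), unit orientation $\hat{\boldsymbol\mu}_i$, magnitude
$\mu_i$ (Debye) and site energy $E_i$ (cm$^{-1}$). Each porphyrin carries
two orthogonal Q-type transitions — one tangent to the ring circle, one
parallel to the ring axis — so that the bare ring can produce a multi-band
Q spectrum *and* possess a symmetry-allowed coupling channel to an axially
polarised dye. The dye is a single transition on the ring axis.

The Frenkel (Davydov) Hamiltonian is

$$H_{ii} = E_i, \qquad
  H_{ij} = \frac{C\,\kappa_{ij}\,\mu_i\mu_j}{n^2 R_{ij}^3},\qquad
  \kappa_{ij} = \hat{\boldsymbol\mu}_i\!\cdot\!\hat{\boldsymbol\mu}_j
  - 3(\hat{\boldsymbol\mu}_i\!\cdot\!\hat R_{ij})
     (\hat{\boldsymbol\mu}_j\!\cdot\!\hat R_{ij}),$$

with $C = 5.0341$ cm$^{-1}$ D$^{-2}$ nm$^3$ (the SI evaluation of
$\mu^2/4\pi\varepsilon_0 R^3$) and solvent screening $1/n^2$, $n = 1.424$
for dichloromethane. The two transitions of one porphyrin share an origin,
where the point-dipole kernel is undefined; their mutual coupling is set to
zero (they are orthogonal electronic states of one chromophore).

Diagonalising $H$ gives exciton states with transition dipoles
$\boldsymbol\mu_k = \sum_i c_{ik}\mu_i\hat{\boldsymbol\mu}_i$. Absorbance is
taken as $A(E) \propto E\,|\boldsymbol\mu_k|^2$ convolved with unit-area
Gaussian lineshapes (FWHM 350 cm$^{-1}$, a typical room-temperature
porphyrin Q-band width) on the energy axis.

In the six-fold symmetric geometry the Hamiltonian is exactly block
diagonal: the tangential manifold carries a bright degenerate pair (its
total in-plane strength), the axial manifold concentrates all its strength
in the totally symmetric combination, and the axial dye couples *only* to
the axial manifold — the orientation factor between an axial dipole and any
tangential dipole vanishes identically, for conformer B (dye displaced
along the axis) just as for conformer A. This is the model's version of the
symmetry selection that makes ring-to-centre transfer in LH1-type
architectures so specific.

```{r model}
m <- lh_model()
m
```

## Energy transfer

Dye-to-band couplings are root-sum-square matrix elements between the dye
basis state and the eigenstates of a band,
$V_b = (\sum_{k\in b}|\langle \mathrm{dye}|H|k\rangle|^2)^{1/2}$, with bands
defined as groups of ring eigenstates separated by less than 50 cm$^{-1}$
(far below the ~800 cm$^{-1}$ inter-manifold gap, so in practice the bands
are the tangential and axial manifolds). The transfer rate per band is the
Fermi golden rule

$$k_b = \frac{2\pi}{\hbar} V_b^2\, J_b, \qquad
  \hbar = \frac{1}{2\pi c} = 5.3088\ \mathrm{cm^{-1}\,ps},$$

i.e. $k_b = 4\pi^2 c\,V_b^2 J_b$ in ps$^{-1}$ with $V_b$ in cm$^{-1}$ and
the spectral overlap $J_b$ in (cm$^{-1}$)$^{-1}$. The constant is not
negotiable: the package's test suite checks it against the exact unitary
dynamics of a donor level coupled to a discretised Lorentzian
quasi-continuum (a Weisskopf–Wigner oracle), which decays at
$2\pi V^2 J/\hbar$ within ~1% in the weak-coupling regime.

$J_b$ is the overlap of the donor emission line — the dye absorption
lineshape red-shifted by a Stokes shift — with the acceptor band lineshape
centred at the band's coupling-weighted mean energy. In the undisordered
model that centre coincides with the bright symmetric axial state, i.e.
exactly the calibrated 810 nm band position.

```{r transfer}
summary(m)
```

## Parameters, defaults, and why

| parameter | default | unit | rationale |
|---|---|---|---|
| `n_sites` | 6 | – | six-porphyrin ring |
| `ring_radius_nm` | 1.2 | nm | centre-to-zinc scale of a butadiyne-linked six-porphyrin ring |
| `dye_offset_B_nm` | 0.4 | nm | conformer B: dye shifted towards one rim |
| `screening_n` | 1.424 | – | refractive index of CH$_2$Cl$_2$, the measurement solvent |
| `fwhm_cm1` | 350 | cm$^{-1}$ | room-temperature porphyrin Q-band width |
| `dye_energy_cm1` | $10^7/725$ | cm$^{-1}$ | dye stick at the 725 nm excitation wavelength used in the quenching experiment |
| `stokes_shift_cm1` | $10^7/725-10^7/798$ | cm$^{-1}$ | places the donor emission line at the observed 798 nm dye emission |
| `sigma_cm1` | 50 | cm$^{-1}$ | modest static disorder, consistent with well-resolved Q-band peaks of a rigid templated ring |
| `delta_E_kJmol` | 0.7 | kJ/mol | conformer A–B energy gap; Boltzmann weights ≈ 57:43 at 298 K |
| `mu_dye_D` | 11 | D | literature scale for Cy7/heptamethine cyanines |
| `mu_tangential_D`, `mu_axial_D` | 0.38, 0.53 | D | *effective* point dipoles, calibrated (below) |

**Calibration.** Site energies are fitted (bounded least squares, L-BFGS-B,
deterministic start at the configured values) so the broadened ring-only
spectrum has its local maxima at the target bands — by default 810 nm
(axial manifold, relative intensity 1) and 760 nm (tangential manifold,
relative intensity 0.55). Peak positions are located by refining grid
maxima with a continuous golden-section search, so the objective varies
smoothly with the parameters and the fit is idempotent.

The dipole magnitudes deserve honesty. A point dipole placed 1.2 nm from an
extended porphyrin transition density substantially overestimates the true
coupling, so the magnitudes used here are *effective* values chosen so that
the model reproduces the observable coupling scale rather than monomer
oscillator strengths. With $\mu_\mathrm{dye}\mu_\mathrm{axial} = 5.83$
D$^2$ the conformer-A dye coupling to the 810 nm band is

$$V_A = \sqrt{6}\,\frac{C\,\mu_\mathrm{dye}\mu_\mathrm{axial}}{n^2 r^3}
      \approx 20.5\ \mathrm{cm^{-1}},$$

consistent with the few-tens-of-cm$^{-1}$ coherent coupling inferred for
this assembly (and of the same order as LH1–reaction-centre couplings).
The resulting kinetics follow with no further freedom: a ~1.6 ps
conformer-A transfer time, a conformer-B inverse mean rate of ~4.4 ps
(the 0.4 nm axial displacement reduces $\kappa$ from 1 to 0.7 and stretches
$R$, scaling $V_B/V_A$ to 0.60), >99% quenching of the dye emission, and
transfer within 50 ps in essentially every ensemble realization.

## What the generator emulates — and what it does not

The synthetic geometry module reproduces the *optically relevant* skeleton:
ring symmetry, the two conformer placements of the dye on the axis, and
frozen Gaussian site-energy disorder (uncorrelated between transitions,
identical statistics for ring and dye). It does not attempt conformational
sampling beyond the two minima, vibronic structure, the Soret band,
charge-transfer or exchange (Dexter) contributions, energy back-transfer
from the ring to the dye, or dynamic (homogeneous) bath physics beyond the
fixed lineshape width. Passing tests therefore validate the exciton/golden-
rule pipeline under these idealisations — they do not certify, for
example, absolute extinction coefficients or temperature dependence.

```{r distribution, fig.alt = "Histogram of simulated dye-to-ring transfer times"}
d <- simulate(m, nsim = 1000, seed = 1)
summary(d)
plot(d)
```

## Numerical choices

* **Diagonalisation** uses LAPACK's symmetric eigensolver; states are
  re-ordered ascending. Degenerate pairs (the tangential bright doublet)
  have an arbitrary gauge; all reported quantities (band couplings, dipole
  strengths summed per band) are gauge-invariant.
* **Band grouping** is single-linkage with a 50 cm$^{-1}$ tolerance on
  adjacent eigenvalue gaps. Under disorder a manifold may occasionally
  split into two bands; rates are summed over bands, so the total is
  insensitive to the split.
* **Band centres** for the overlap integral are coupling-weighted mean
  energies ($\sum V_k^2 E_k / \sum V_k^2$), falling back to the plain mean
  for dark bands (plotting only).
* **Spectral overlaps** use closed forms for Gaussian–Gaussian and
  Lorentzian–Lorentzian pairs and adaptive quadrature on a finite window
  (±200 FWHM) for mixed shapes.
* **Degenerate inputs**: a fully decoupled dye yields total rate 0 and a
  flagged infinite transfer time rather than an error; zero-sigma disorder
  reproduces the deterministic result exactly.
* **Reproducibility**: every stochastic routine takes an explicit integer
  seed, uses one private RNG stream, restores the caller's stream, and is
  bitwise reproducible. Monte-Carlo summaries carry bootstrap 95%
  percentile intervals (500 replicates).

**Problem sizes.** The full assembly is a 13-state Hamiltonian, so a
5000-realization ensemble diagonalises 5000 12×12 ring blocks in a few
seconds. The vignette and tests use 100–2000 realizations; the bundled
acceptance script uses 2000 per conformer and 5000 for the combined
ensemble, which brings the Monte-Carlo error on the reported medians and
mean rates well below the percent level.

## Inverting the fluorescence quenching

Independently of the exciton model, the measured donor-channel brightness
ratio $r$ and free-donor lifetime $\tau_\mathrm{fl}$ bound the transfer
time through the rate competition
$r = (1/\tau_\mathrm{fl})/(1/\tau_\mathrm{fl} + k_\mathrm{ET})$, i.e.
$\tau_\mathrm{ET} = r\,\tau_\mathrm{fl}/(1-r)$:

```{r quenching}
print(kinetic_scheme())  # r = 0.0051, tau_fl = 0.97 ns
```

The ~5 ps desk estimate and the ~1.6–4.4 ps microscopic ensemble agree at
the level this comparison can support; feeding the ensemble-mean rate back
through the competition formula predicts $r < 0.01$, i.e. the observed
>99% quenching. The competition form (rather than the cruder product
$r\,\tau_\mathrm{fl}$) is adopted because it is exact for a two-channel
kinetic scheme; both give sub-10-ps times here. The brightness ratio is
treated as a pure donor-channel yield ratio — contamination of the 798 nm
channel by ring emission is neglected, justified because the ring emits at
910 nm.

## Known limitations

* Point dipoles with calibrated effective magnitudes reproduce coupling
  *scales*, not ab-initio values; extended-dipole or transition-charge
  kernels would be the next refinement (the coupling kernel is isolated in
  `dipole_coupling()` for exactly that reason).
* The three-peak structure of the experimental Q band is richer than the
  two bright manifolds this minimal model produces; calibration accepts
  any number of target bands but can only place as many maxima as the
  model owns.
* Golden-rule transfer assumes weak dye–ring coupling; at
  $V/\Gamma \approx 0.06$ the second-order treatment is comfortably valid
  (corrections enter at $(2V/\Gamma)^2 \approx 1\%$).
* Conformer weights use a fixed gap of 0.7 kJ/mol; no attempt is made to
  model the ms-scale A/B interconversion dynamics, which is irrelevant on
  the ps transfer timescale.
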