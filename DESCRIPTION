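Package: excitonring
Title: Frenkel Exciton Modelling of a Dye-in-Nanoring Light-Harvesting Assembly
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and analyses a Frenkel (Davydov) exciton model of an
    artificial light-harvesting complex in which a near-infrared cyanine dye is
    held on the axis of a six-porphyrin zinc nanoring, mimicking the LH1 antenna
    ring around the bacterial reaction centre. The package generates the
    ring-plus-axial-dye geometry (including the two low-energy conformers and
    Gaussian static site-energy disorder), assembles and diagonalises the
    point-dipole exciton Hamiltonian, simulates stick and broadened absorption
    spectra and their additivity, computes dye-to-ring couplings and
    second-order perturbation-theory (golden-rule) energy-transfer rates and
    transfer-time distributions over conformer and disorder ensembles, and
    inverts fluorescence-quenching observables (brightness ratio, donor
    lifetime) into energy-transfer time estimates.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
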