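Package: fmoexciton
Title: Frenkel Exciton Model and Bath Characterization for Pigment-Protein Complexes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the excitonic analysis of pigment-protein complexes such
    as the Fenna-Matthews-Olson (FMO) light-harvesting complex. Builds Frenkel
    exciton Hamiltonians from site energies and point-dipole excitonic
    couplings, diagonalizes them to obtain exciton energies and per-pigment
    contributions, and computes stick and Gaussian-broadened absorption
    spectra. Characterizes the protein bath from site-energy time series via
    autocorrelation functions, biexponential fits with a white-noise-residue
    fast component, and Drude spectral densities, and aggregates per-pigment
    bath parameters into transport descriptors. Includes seeded generators for
    Ornstein-Uhlenbeck site-energy trajectories, toy pigment geometries, and
    jittered coordinate trajectories so the full pipeline is testable without
    upstream molecular-dynamics or quantum-chemistry calculations, plus
    structural trajectory statistics (Kabsch superposition RMSD, Mg-N distance
    distributions and their full widths at half maximum).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    graphics,
    jsonlite,
    minpack.lm,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
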