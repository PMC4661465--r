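---
title: "Exciton models and bath characterization for pigment-protein complexes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exciton models and bath characterization for pigment-protein complexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fmoexciton)
```

## The model

The optical properties of a pigment-protein complex such as the
Fenna-Matthews-Olson (FMO) trimer are described here by a Frenkel exciton
Hamiltonian over the Qy excitations of its bacteriochlorophylls (BChls):

$$H = \sum_k E_k |k\rangle\langle k| + \sum_{k \neq m} V_{km}
      |k\rangle\langle m|,$$

with site energies $E_k$ (the excitation energy of pigment $k$ in its
protein pocket) on the diagonal and excitonic couplings $V_{km}$
off-diagonal, everything in cm$^{-1}$. Diagonalizing $H$ gives delocalized
exciton levels; the *contribution* of pigment $k$ to level $\alpha$ is the
squared component $c_{\alpha k}^2$ of the real orthonormal eigenvector, so
contribution rows sum to one and the exciton energies sum to the trace of
$H$. Those two identities are enforced as package invariants rather than
assumed.

Couplings are computed in the point-dipole approximation,

$$V_{km} = f\,\frac{5.034\,\mu_k \mu_m\,\kappa_{km}}{R_{km}^{3}},
  \qquad
  \kappa_{km} = \hat e_k \cdot \hat e_m
  - 3(\hat e_k \cdot \hat r_{km})(\hat e_m \cdot \hat r_{km}),$$

with $R_{km}$ the Mg-Mg distance in Angstrom, dipole strengths in Debye and
the prefactor 5.034 converting D$^2$/A$^3$ to cm$^{-1}$. Defaults are the
values standard in FMO work: screening $f = 0.8$ and
$\mu_k\mu_m = 37.5\,$D$^2$ for all pairs. The dipole direction of a BChl is
taken from atom ND to atom NB (PDB nomenclature). $\kappa$ is even in
$\hat r$, so the orientation factor does not depend on which pigment is
taken as the origin.

The protein environment ("bath") of each pigment is characterized from the
fluctuations $\Delta E(t) = E(t) - \langle E \rangle$ of its site-energy
time series. The monomer-averaged autocorrelation function

$$C(t_j) = \frac{1}{N_l}\sum_l \frac{1}{N} \sum_i
  \Delta E_l(t_i + t_j)\,\Delta E_l(t_i)$$

is fitted by a biexponential, $C(t) \approx a\,e^{-t/\tau_{\mathrm{slow}}}
+ b\,e^{-t/\tau_{\mathrm{fast}}}$, whose fast part plays the role of a
white-noise residue. The classical fluctuation-dissipation relation at high
temperature maps the slow amplitude to the reorganization energy,
$\lambda = a/(2 k_B T)$ with $k_B T$ in cm$^{-1}$, and the slow timescale
to the Drude cutoff $\gamma = 1/(2\pi c\,\tau_{\mathrm{slow}})$ of the
spectral density

$$J(\omega) = \frac{2\lambda\gamma\omega}{\omega^2 + \gamma^2},$$

which peaks at $\omega = \gamma$ with $J(\gamma) = \lambda$. The same
$C(t)$ can instead be transformed directly,
$J(\omega) = \beta\,\omega \int_0^\infty C(t)\cos(\omega t)\,dt$ (with
$\omega$ as an angular frequency $2\pi c\,\tilde\nu$), and for a pure
exponential the two routes coincide exactly under the conventions above.
That exact consistency is what fixes the otherwise ambiguous
timescale-to-wavenumber convention: the mean slow timescale of 16.07 fs
across the eight pigments corresponds to a cutoff of 330 cm$^{-1}$ only
with the $2\pi c$ convention, so that convention is adopted throughout.

## Embedded reference model

The package embeds the published eight-site FMO monomer Hamiltonian
(`fmo_site_hamiltonian()`) and the published per-pigment bath parameters
(`fmo_bath_parameters()`). The printed Hamiltonian table has a layout
ambiguity around pigment 8: it lists a weak intra-monomer coupling row "8"
without a site energy, and an inter-monomer row "8'" (pigment 8 of the
neighboring monomer) with site energy 11486 cm$^{-1}$. Both variants use
11486 cm$^{-1}$ as pigment 8's diagonal, and both reproduce all eight
exciton energies to better than 0.001 eV. They differ in the
contributions: the top two exciton levels are separated by only
$\sim$0.001 eV, and near-degenerate eigenvectors are sensitive to the weak
couplings to pigment 8. The 8'-row variant reproduces every published
contribution to within 0.005 (including pigment 8's 0.80 at the 1.424 eV
level), while the intra-row variant misses several by up to 0.21. The
8' variant is therefore the default; the intra variant remains available
via `fmo_site_hamiltonian("intra")`.

```{r}
r <- diagonalize(fmo_site_hamiltonian())
round(exciton_table(r)[, c("level", "energy_ev", "pigment_3", "pigment_8")], 3)
```

## What the synthetic generator emulates

The upstream stages of the original workflow - structure preparation, MD
sampling, and QM/MM site-energy calculations - are out of scope here and
are replaced by seeded generators:

* `generate_ou_site_energies()` draws stationary Gaussian site-energy
  trajectories with exponential memory (an Ornstein-Uhlenbeck process),
  using the exact discretization
  $X_{n+1} = X_n e^{-\Delta t/\tau} + \sqrt{\sigma^2(1 - e^{-2\Delta
  t/\tau})}\,\xi_n$ with stationary variance $\sigma^2 = 2\lambda k_B T$.
  Defaults mirror the production conditions of the study this package
  models: 20 ps at a 0.5 fs step (40,000 samples), three monomers, 300 K,
  $\lambda = 100$ cm$^{-1}$, $\tau = 15$ fs, mean site energy
  11450 cm$^{-1}$ (mid-range of the eight-site ladder).
* `generate_pigment_ring()` places pigments on a circle with tangential,
  parallel or random unit dipoles - enough geometric structure to exercise
  every coupling and exciton code path.
* `generate_jittered_trajectory()` adds isotropic Gaussian jitter and
  optional random rigid motion to a base structure, the minimal model for
  superposition-RMSD and distance-distribution statistics.

An OU bath is exactly the process the Drude model describes, so parameter
recovery on OU data is a genuine end-to-end test of the estimation chain.
What the generator deliberately does *not* emulate: non-Gaussian and
multi-timescale protein dynamics, vibronic structure, correlated
fluctuations between pigments, and any quantum (imaginary) part of $C(t)$.
Passing the recovery tests therefore validates the estimator chain, not
the realism of MD data.

## Numerical choices

* **Autocorrelation estimator.** The biased form (divide by the full
  length $N$, not $N - j$) is used at every lag; it decays smoothly and
  matches standard spectral practice. `C(0)` is then exactly the pooled
  biased variance. The default lag window is
  $\min(2000\ \mathrm{fs}, (N-1)\Delta t/2)$.
* **Fit strategy.** The default, unconstrained mode runs bounded
  Levenberg-Marquardt from multiple starts (fast-timescale initializations
  spread below a log-linear tail estimate of the slow timescale). A
  biexponential on noisy single-timescale data can split its amplitude
  between two nearly equal timescales or attach a spurious slow component
  to the statistical noise tail; fits whose timescales differ by less than
  a factor of two, or whose slow amplitude falls below 20% of the fast
  one, are treated as unidentifiable and replaced by the single-exponential
  fit (zero fast amplitude). Genuinely separated pairs such as 15 fs / 4 fs
  are unaffected.
* **Constrained mode.** The alternative fit mode fixes the fast timescale
  at the thermal (first Matsubara) time $\hbar\beta/2\pi \approx 4.05$ fs
  at 300 K, which depends on temperature only. This is the package's own
  stand-in for the temperature-fixed fast-modulation constraint of the
  white-noise-residue treatment; the exact published parameter relations
  were not available to transcribe, so the constrained mode is documented
  as provisional and the unconstrained mode is the tested default.
* **Spectral-density quadrature.** The cosine transform uses trapezoidal
  quadrature on the supplied lag grid and warns when $C(t)$ has not
  decayed below 5% of $C(0)$ by the last lag. For noisy estimated
  correlation functions the transform should be given a window truncated
  just past the decay (about $8\tau$); integrating thousands of
  noise-dominated lags degrades $J(\omega)$ far more than truncation does.
  Consistency between the fitted Drude curve and the direct transform is
  checked band-averaged over $[0.8\gamma, 1.2\gamma]$, i.e. "near the
  peak", where the Drude form is informative.
* **Transport descriptor.** `transport_parameter()` evaluates a
  dimensionless combination of $\lambda$, $\gamma$, the mean exciton gap
  $g$ (span/$(n-1)$ of the exciton ladder) and $k_B T$. The default
  $\lambda\gamma/(g\,k_B T)$ is an explicit placeholder - the published
  definition of this descriptor was not available to transcribe - and any
  alternative can be plugged in as a function. No published value of the
  descriptor is claimed to be reproduced.
* **Superposition.** RMSD uses the closed-form Kabsch rotation (SVD with
  determinant correction to exclude reflections) on the selected atoms;
  a no-refit mode computes plain coordinate RMSD. Degenerate eigenvalues in
  `diagonalize()` produce a warning and are reported per returned
  eigenvector without subspace rotation.
* **Histogram widths.** `histogram_fwhm()` fits a three-parameter Gaussian
  to histogram counts (default bin width 0.01 A) and reports
  $2\sqrt{2\ln 2}\,\sigma$; if the fit fails it falls back to the
  empirical half-maximum crossing width and flags that in its output.

## Problem sizes used in tests and drivers

The test-suite and the `analysis/` drivers work at the production scale of
the modeled study where that is what is being claimed - bath recovery runs
20 ps / 0.5 fs / 3 monomers per pigment, with a 10-seed median for the
recovery property - and at reduced demonstration scale elsewhere (the
committed demonstration table is 0.25 ps; structural statistics use 1500-2000
frames of a 10-atom model). Exciton-model checks are exact and instantaneous
at $n = 8$; invariants are exercised up to $n = 24$ (a full trimer's worth
of pigments).

## Known limitations

* Absolute site energies cannot be computed here; they enter only through
  the embedded reference table or user input. The package reproduces the
  *diagonalization* of the published model, not its upstream QM/MM values.
* The point-dipole approximation degrades at close pigment separations
  where transition-charge methods would be needed; no such scheme is
  included.
* The bath treatment is classical and Markovian-with-residue: no imaginary
  part of $C(t)$, no Matsubara corrections beyond the fixed fast timescale,
  no multi-peak or Ohmic spectral densities, and no exciton population
  dynamics on top of the fitted bath.
* Near-degenerate exciton levels make individual contribution rows
  basis-sensitive; the package warns rather than rotating the subspace,
  and the embedded model's top two levels are exactly such a pair.
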