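# Published eight-level exciton decomposition of the FMO monomer model:
# energies in eV (levels listed highest first) and per-pigment contributions.
reference_exciton_energies_ev <- c(1.439, 1.438, 1.427, 1.424,
                                   1.419, 1.411, 1.407, 1.400)

reference_exciton_contributions <- matrix(c(
  0.38, 0.09, 0.00, 0.06, 0.08, 0.23, 0.10, 0.04,
  0.38, 0.08, 0.00, 0.14, 0.15, 0.18, 0.06, 0.01,
  0.00, 0.00, 0.01, 0.08, 0.07, 0.25, 0.57, 0.02,
  0.02, 0.07, 0.02, 0.05, 0.02, 0.03, 0.00, 0.80,
  0.00, 0.00, 0.05, 0.29, 0.17, 0.20, 0.19, 0.10,
  0.16, 0.49, 0.23, 0.00, 0.07, 0.02, 0.01, 0.02,
  0.04, 0.18, 0.10, 0.17, 0.36, 0.09, 0.05, 0.01,
  0.01, 0.09, 0.59, 0.20, 0.08, 0.00, 0.02, 0.00),
  nrow = 8, byrow = TRUE,
  dimnames = list(level = NULL, pigment = as.character(1:8)))

random_unit_vector <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

random_pigments <- function(n, box = 30, monomer = "A") {
  lapply(seq_len(n), function(i)
    pigment_geometry(as.character(i), monomer,
                     stats::runif(3, 0, box) + c(3 * i, 0, 0),
                     random_unit_vector()))
}

# independent brute-force point-dipole coupling from the raw formula
brute_force_coupling <- function(p_k, p_m, f = 0.8, mu2 = 37.5) {
  r <- p_m$mg_position - p_k$mg_position
  R <- sqrt(sum(r^2))
  rh <- r / R
  ek <- p_k$dipole_direction; em <- p_m$dipole_direction
  kap <- sum(ek * em) - 3 * sum(ek * rh) * sum(em * rh)
  f * 5.034 * mu2 * kap / R^3
}
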