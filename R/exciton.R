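#' Frenkel exciton Hamiltonian
#'
#' A labeled symmetric matrix in cm^-1: site energies on the diagonal,
#' excitonic couplings off-diagonal. The matrix is validated to be symmetric
#' within 1e-6 cm^-1 (asymmetries above 1e-3 trigger a warning before
#' symmetrization by averaging).
#'
#' @param labels Character vector of pigment labels (unique).
#' @param matrix Square numeric matrix, cm^-1.
#' @return An object of class `exciton_hamiltonian` (list with `labels` and
#'   `matrix`).
#' @export
exciton_hamiltonian <- function(labels, matrix) {
  labels <- as.character(labels)
  stopifnot(is.matrix(matrix), nrow(matrix) == ncol(matrix),
            nrow(matrix) == length(labels))
  if (anyDuplicated(labels)) stop("pigment labels must be unique")
  if (!all(is.finite(matrix))) stop("Hamiltonian contains non-finite entries")
  asym <- max(abs(matrix - t(matrix)))
  if (asym > 1e-3)
    warning("Hamiltonian asymmetry ", format(asym),
            " cm^-1 exceeds 1e-3; symmetrizing by averaging")
  m <- (matrix + t(matrix)) / 2
  dimnames(m) <- list(labels, labels)
  structure(list(labels = labels, matrix = m), class = "exciton_hamiltonian")
}

#' @export
print.exciton_hamiltonian <- function(x, ...) {
  cat(sprintf("<exciton Hamiltonian> %d pigments, trace = %.1f cm^-1\n",
              length(x$labels), sum(diag(x$matrix))))
  print(round(x$matrix, 2))
  invisible(x)
}

#' Assemble a Frenkel Hamiltonian from site energies and couplings
#'
#' @param site_energies Named numeric vector of site energies (cm^-1); names
#'   are pigment labels.
#' @param couplings Labeled symmetric matrix of couplings (cm^-1); its label
#'   set must equal that of `site_energies`. The diagonal of `couplings` is
#'   ignored. May be `NULL` for a purely diagonal Hamiltonian.
#' @return An `exciton_hamiltonian`.
#' @export
build_hamiltonian <- function(site_energies, couplings = NULL) {
  labels <- names(site_energies)
  if (is.null(labels) || anyDuplicated(labels))
    stop("site_energies must carry unique names")
  if (is.null(couplings)) {
    m <- diag(as.numeric(site_energies), nrow = length(site_energies))
  } else {
    stopifnot(is.matrix(couplings))
    if (!setequal(rownames(couplings), labels) ||
        !setequal(colnames(couplings), labels))
      stop("label sets of site_energies and couplings differ")
    m <- couplings[labels, labels, drop = FALSE]
    diag(m) <- as.numeric(site_energies)
  }
  exciton_hamiltonian(labels, m)
}

#' Diagonalize a Frenkel Hamiltonian
#'
#' Computes the delocalized exciton states. Exciton energies are stored in
#' ascending order; the per-pigment contribution of pigment i to level alpha
#' is the squared (real, orthonormal) eigenvector component, so each
#' contribution row sums to 1 and the energies sum to the Hamiltonian trace.
#' Use [exciton_table()] for the conventional descending-energy presentation.
#'
#' @param h An `exciton_hamiltonian`.
#' @return An object of class `exciton_result`: list with `labels`,
#'   `energies_cm1` (ascending), `energies_ev`, `contributions` (rows =
#'   levels ascending, columns = pigments), `eigenvectors` (columns = levels).
#' @export
diagonalize <- function(h) {
  stopifnot(inherits(h, "exciton_hamiltonian"))
  e <- eigen(h$matrix, symmetric = TRUE)
  ord <- order(e$values)            # eigen() returns descending; store ascending
  vals <- e$values[ord]
  vecs <- e$vectors[, ord, drop = FALSE]
  if (length(vals) > 1L && min(diff(vals)) < 1e-9 * max(1, abs(vals[length(vals)])))
    warning("near-degenerate exciton levels: contributions are reported per ",
            "returned eigenvector, no subspace rotation applied")
  contrib <- t(vecs^2)
  dimnames(contrib) <- list(level = NULL, pigment = h$labels)
  structure(
    list(labels = h$labels,
         energies_cm1 = vals,
         energies_ev = cm1_to_ev(vals),
         contributions = contrib,
         eigenvectors = vecs),
    class = "exciton_result")
}

#' Exciton levels as a presentation table
#'
#' @param result An `exciton_result`.
#' @param order `"descending"` (highest level first, the conventional listing)
#'   or `"ascending"`.
#' @return A data.frame with level index, energies in cm^-1 and eV, and one
#'   contribution column per pigment.
#' @export
exciton_table <- function(result, order = c("descending", "ascending")) {
  stopifnot(inherits(result, "exciton_result"))
  order <- match.arg(order)
  n <- length(result$energies_cm1)
  idx <- if (order == "descending") n:1 else 1:n
  out <- data.frame(level = seq_len(n),
                    energy_cm1 = result$energies_cm1[idx],
                    energy_ev = result$energies_ev[idx])
  contrib <- result$contributions[idx, , drop = FALSE]
  colnames(contrib) <- paste0("pigment_", result$labels)
  cbind(out, as.data.frame(contrib))
}

#' @export
print.exciton_result <- function(x, digits = 3, ...) {
  cat(sprintf("<exciton result> %d levels, %.3f-%.3f eV\n",
              length(x$energies_cm1), min(x$energies_ev), max(x$energies_ev)))
  print(round(exciton_table(x), digits))
  invisible(x)
}

#' Element-wise average of Hamiltonian snapshots
#'
#' Averages per-snapshot Hamiltonians (e.g. computed along a trajectory) into
#' a mean Hamiltonian with the same labels.
#'
#' @param snapshots Non-empty list of `exciton_hamiltonian` objects with
#'   identical labels.
#' @return An `exciton_hamiltonian`.
#' @export
average_hamiltonian <- function(snapshots) {
  if (!is.list(snapshots) || length(snapshots) == 0L)
    stop("snapshots must be a non-empty list")
  labels <- snapshots[[1L]]$labels
  for (s in snapshots) {
    stopifnot(inherits(s, "exciton_hamiltonian"))
    if (!identical(s$labels, labels))
      stop("all snapshots must share identical labels")
  }
  m <- Reduce(`+`, lapply(snapshots, `[[`, "matrix")) / length(snapshots)
  exciton_hamiltonian(labels, m)
}

#' Absorption spectrum from an exciton decomposition
#'
#' The transition dipole of exciton alpha is the coefficient-weighted vector
#' sum of the pigment dipoles, mu_alpha = sum_i c_alpha,i mu_i; the stick
#' intensity is |mu_alpha|^2. Sticks are convolved with a unit-area Gaussian
#' of the given FWHM. By unitarity the integrated intensity equals the sum of
#' the pigment dipole strengths.
#'
#' @param result An `exciton_result`.
#' @param pigment_dipoles Numeric matrix (n_pigments x 3) of transition-dipole
#'   vectors in Debye, rows ordered as `result$labels`.
#' @param grid Energy axis in cm^-1; defaults to the stick range padded by
#'   4 FWHM at FWHM/20 resolution.
#' @param fwhm Gaussian full width at half maximum in cm^-1 (> 0).
#' @return List with `axis` (cm^-1), `intensity` (D^2 per cm^-1),
#'   `stick_energies` and `stick_intensities`.
#' @export
absorption_spectrum <- function(result, pigment_dipoles, grid = NULL, fwhm = 80) {
  stopifnot(inherits(result, "exciton_result"), is.numeric(fwhm), fwhm > 0)
  pigment_dipoles <- as.matrix(pigment_dipoles)
  n <- length(result$labels)
  if (nrow(pigment_dipoles) != n || ncol(pigment_dipoles) != 3L)
    stop("pigment_dipoles must be an n_pigments x 3 matrix")
  mu_exciton <- t(result$eigenvectors) %*% pigment_dipoles
  sticks <- rowSums(mu_exciton^2)
  energies <- result$energies_cm1
  if (is.null(grid)) {
    grid <- seq(min(energies) - 4 * fwhm, max(energies) + 4 * fwhm,
                by = fwhm / 20)
  }
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  intensity <- rep(0, length(grid))
  for (a in seq_len(n))
    intensity <- intensity + sticks[a] * stats::dnorm(grid, energies[a], sigma)
  list(axis = grid, intensity = intensity,
       stick_energies = energies, stick_intensities = sticks)
}

#' Average excitonic energy gap
#'
#' Mean spacing of adjacent exciton levels, i.e. (highest - lowest)/(n - 1).
#' This is the gap scale g entering dimensionless transport descriptors.
#'
#' @param result An `exciton_result` with at least 2 levels.
#' @return The mean adjacent-level gap in cm^-1.
#' @export
average_excitonic_gap <- function(result) {
  stopifnot(inherits(result, "exciton_result"))
  n <- length(result$energies_cm1)
  if (n < 2L) stop("need at least 2 exciton levels")
  (max(result$energies_cm1) - min(result$energies_cm1)) / (n - 1L)
}
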