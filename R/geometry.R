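#' Pigment geometry
#'
#' A pigment is reduced to its Mg position (the coupling distance reference)
#' and the unit direction of its Qy transition dipole (ND -> NB in PDB
#' nomenclature for bacteriochlorophyll).
#'
#' @param label Pigment identifier (e.g. "1".."8").
#' @param monomer Monomer identifier (chain); pigments in different monomers
#'   are coupled like any other pair, the label only tags provenance.
#' @param mg_position Numeric length-3, Mg coordinates in Angstrom.
#' @param dipole_direction Numeric length-3; normalized internally, must be
#'   non-zero and within 1e-6 of unit length if already normalized data is
#'   passed.
#' @return An object of class `pigment_geometry`.
#' @examples
#' pigment_geometry("1", "A", c(0, 0, 0), c(0, 0, 1))
#' @export
pigment_geometry <- function(label, monomer, mg_position, dipole_direction) {
  stopifnot(length(mg_position) == 3L, all(is.finite(mg_position)),
            length(dipole_direction) == 3L, all(is.finite(dipole_direction)))
  nrm <- sqrt(sum(dipole_direction^2))
  if (nrm < 1e-12)
    stop("dipole_direction has zero length for pigment '", label, "'")
  structure(
    list(label = as.character(label), monomer = as.character(monomer),
         mg_position = as.numeric(mg_position),
         dipole_direction = as.numeric(dipole_direction) / nrm),
    class = "pigment_geometry")
}

#' @export
print.pigment_geometry <- function(x, ...) {
  cat(sprintf("<pigment %s/%s> Mg = (%.3f, %.3f, %.3f) A, dipole = (%.4f, %.4f, %.4f)\n",
              x$label, x$monomer,
              x$mg_position[1], x$mg_position[2], x$mg_position[3],
              x$dipole_direction[1], x$dipole_direction[2], x$dipole_direction[3]))
  invisible(x)
}

#' Point-dipole coupling configuration
#'
#' Defaults are the standard FMO values: protein screening factor f = 0.8 and
#' transition-dipole strength product mu_k mu_m = 37.5 D^2, applied uniformly
#' to all pairs (intra- and inter-monomer).
#'
#' @param screening_factor Dimensionless screening f (> 0).
#' @param dipole_strength_product mu_k mu_m in Debye^2 (> 0).
#' @return An object of class `coupling_config`.
#' @export
coupling_config <- function(screening_factor = 0.8, dipole_strength_product = 37.5) {
  stopifnot(is.numeric(screening_factor), screening_factor > 0,
            is.numeric(dipole_strength_product), dipole_strength_product > 0)
  structure(list(screening_factor = screening_factor,
                 dipole_strength_product = dipole_strength_product),
            class = "coupling_config")
}

.check_unit <- function(v, name, tol = 1e-6) {
  if (length(v) != 3L || !all(is.finite(v)))
    stop(name, " must be a finite 3-vector")
  if (abs(sqrt(sum(v^2)) - 1) > tol)
    stop(name, " is not a unit vector (|", name, "| = ",
         format(sqrt(sum(v^2))), ")")
  invisible(v)
}

#' Orientation factor of the point-dipole coupling
#'
#' kappa = e_k . e_m - 3 (e_k . r_hat)(e_m . r_hat), bounded in \[-2, 2\].
#' kappa is even in r_hat, so the choice of separation direction (k -> m or
#' m -> k) does not matter.
#'
#' @param e_k,e_m Unit transition-dipole directions.
#' @param r_hat Unit vector along the Mg-Mg separation.
#' @return The dimensionless orientation factor.
#' @examples
#' orientation_factor(c(0, 0, 1), c(0, 0, 1), c(1, 0, 0))  # parallel, perp: 1
#' orientation_factor(c(1, 0, 0), c(1, 0, 0), c(1, 0, 0))  # head-to-tail: -2
#' @export
orientation_factor <- function(e_k, e_m, r_hat) {
  .check_unit(e_k, "e_k"); .check_unit(e_m, "e_m"); .check_unit(r_hat, "r_hat")
  sum(e_k * e_m) - 3 * sum(e_k * r_hat) * sum(e_m * r_hat)
}

#' Excitonic coupling in the point-dipole approximation
#'
#' V = f * 5.034 * (mu_k mu_m) * kappa / R^3, with R the Mg-Mg distance in
#' Angstrom, dipole strengths in Debye and V in cm^-1.
#'
#' @param pig_k,pig_m `pigment_geometry` objects.
#' @param config A `coupling_config`.
#' @return Coupling in cm^-1.
#' @examples
#' p1 <- pigment_geometry("1", "A", c(0, 0, 0), c(0, 0, 1))
#' p2 <- pigment_geometry("2", "A", c(10, 0, 0), c(0, 0, 1))
#' point_dipole_coupling(p1, p2)  # kappa = 1, R = 10 A
#' @export
point_dipole_coupling <- function(pig_k, pig_m, config = coupling_config()) {
  stopifnot(inherits(pig_k, "pigment_geometry"),
            inherits(pig_m, "pigment_geometry"),
            inherits(config, "coupling_config"))
  r <- pig_m$mg_position - pig_k$mg_position
  R <- sqrt(sum(r^2))
  if (R <= 0.1)
    stop("Mg positions of pigments '", pig_k$label, "' and '", pig_m$label,
         "' are coincident (R = ", format(R), " A)")
  kappa <- orientation_factor(pig_k$dipole_direction, pig_m$dipole_direction, r / R)
  uc <- unit_constants()
  config$screening_factor * uc$dipole_coupling_prefactor *
    config$dipole_strength_product * kappa / R^3
}

#' Pairwise point-dipole coupling matrix
#'
#' @param pigments List of `pigment_geometry` objects with distinct labels.
#' @param config A `coupling_config`.
#' @return Labeled symmetric matrix of couplings in cm^-1 with zero diagonal.
#' @export
coupling_matrix <- function(pigments, config = coupling_config()) {
  stopifnot(is.list(pigments), length(pigments) >= 2L)
  labels <- vapply(pigments, function(p) p$label, character(1))
  if (anyDuplicated(labels))
    stop("duplicate pigment labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  n <- length(pigments)
  V <- matrix(0, n, n, dimnames = list(labels, labels))
  for (k in seq_len(n - 1L)) {
    for (m in (k + 1L):n) {
      v <- point_dipole_coupling(pigments[[k]], pigments[[m]], config)
      V[k, m] <- v
      V[m, k] <- v
    }
  }
  V
}
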