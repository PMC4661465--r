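#' Site-energy trajectory
#'
#' An evenly sampled time series of the excitation (Qy) energy of one pigment
#' in one monomer, in cm^-1.
#'
#' @param pigment_label,monomer_label Identifiers.
#' @param time_step Sampling interval in fs (> 0).
#' @param energies Numeric vector of site energies in cm^-1 (length >= 2,
#'   finite).
#' @return An object of class `site_energy_trajectory`.
#' @export
site_energy_trajectory <- function(pigment_label, monomer_label, time_step, energies) {
  stopifnot(is.numeric(time_step), length(time_step) == 1L, time_step > 0,
            is.numeric(energies), length(energies) >= 2L)
  if (!all(is.finite(energies))) stop("energies must be finite")
  structure(
    list(pigment_label = as.character(pigment_label),
         monomer_label = as.character(monomer_label),
         time_step = as.numeric(time_step),
         energies = as.numeric(energies)),
    class = "site_energy_trajectory")
}

#' @export
print.site_energy_trajectory <- function(x, ...) {
  cat(sprintf("<site-energy trajectory> pigment %s, monomer %s: %d samples @ %g fs, mean %.1f cm^-1\n",
              x$pigment_label, x$monomer_label, length(x$energies),
              x$time_step, mean(x$energies)))
  invisible(x)
}

.stop_if_empty <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0L) stop("empty file: ", path)
  invisible(path)
}

#' Read pigment geometries from a PDB file
#'
#' Extracts one [pigment_geometry()] per bacteriochlorophyll-like residue:
#' the Mg position is the MG atom coordinate and the transition-dipole
#' direction the unit vector from atom ND to atom NB (PDB nomenclature).
#' Residue number and chain are preserved as pigment and monomer labels.
#'
#' @param path PDB file.
#' @param residue_names Residue names treated as pigments.
#' @return List of `pigment_geometry` objects.
#' @export
read_pigments_from_pdb <- function(path, residue_names = c("BCL", "BCHL")) {
  .stop_if_empty(path)
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  atoms <- pdb$atom
  sel <- atoms$resid %in% residue_names
  if (!any(sel)) stop("no residues named ", paste(residue_names, collapse = "/"),
                      " in ", path)
  atoms <- atoms[sel, , drop = FALSE]
  atoms$chain[is.na(atoms$chain)] <- ""
  key <- paste(atoms$chain, atoms$resno, sep = "/")
  out <- list()
  for (k in unique(key)) {
    res <- atoms[key == k, , drop = FALSE]
    coord_of <- function(name) {
      i <- which(res$elety == name)
      if (length(i) != 1L)
        stop("residue ", res$resid[1], " ", k, " is missing atom ", name)
      as.numeric(res[i, c("x", "y", "z")])
    }
    mg <- coord_of("MG"); nd <- coord_of("ND"); nb <- coord_of("NB")
    if (sqrt(sum((nb - nd)^2)) < 1e-6)
      stop("zero-length ND->NB vector in residue ", res$resid[1], " ", k)
    out[[length(out) + 1L]] <- pigment_geometry(
      label = as.character(res$resno[1]), monomer = res$chain[1],
      mg_position = mg, dipole_direction = nb - nd)
  }
  out
}

#' Write pigment geometries to a PDB file
#'
#' Emits one residue per pigment with MG at the Mg position and ND/NB placed
#' symmetrically about Mg along the dipole direction, so that
#' [read_pigments_from_pdb()] recovers positions (to the 1e-3 A precision of
#' the PDB format) and dipole directions exactly.
#'
#' @param pigments List of `pigment_geometry` objects.
#' @param path Output file.
#' @param residue_name Residue name to write (default "BCL").
#' @param nd_nb_distance ND-NB separation in Angstrom.
#' @return `path`, invisibly.
#' @export
write_pigments_pdb <- function(pigments, path, residue_name = "BCL",
                               nd_nb_distance = 2.9) {
  stopifnot(is.list(pigments), length(pigments) >= 1L)
  n <- length(pigments)
  xyz <- matrix(0, 1L, 9L * n)
  resno <- integer(0); chain <- character(0)
  for (i in seq_len(n)) {
    p <- pigments[[i]]
    half <- (nd_nb_distance / 2) * p$dipole_direction
    xyz[1, (9L * (i - 1L) + 1L):(9L * i)] <-
      c(p$mg_position, p$mg_position - half, p$mg_position + half)
    rn <- suppressWarnings(as.integer(p$label))
    resno <- c(resno, rep(if (is.na(rn)) i else rn, 3L))
    ch <- substr(p$monomer, 1L, 1L)
    chain <- c(chain, rep(if (nzchar(ch)) ch else "A", 3L))
  }
  bio3d::write.pdb(file = path, xyz = xyz, resno = resno, chain = chain,
                   resid = rep(residue_name, 3L * n),
                   elety = rep(c("MG", "ND", "NB"), n),
                   eleno = seq_len(3L * n))
  invisible(path)
}

#' Read a site-energy table
#'
#' Reads a comma-delimited table with columns `time_fs`, `pigment`,
#' `monomer`, `energy_cm1` into one [site_energy_trajectory()] per
#' (pigment, monomer) pair. The time grid of each pair must be uniform
#' (relative jitter below 1e-6).
#'
#' @param path CSV file.
#' @return List of `site_energy_trajectory` objects.
#' @export
read_site_energy_table <- function(path) {
  .stop_if_empty(path)
  tab <- utils::read.csv(path, check.names = FALSE)
  needed <- c("time_fs", "pigment", "monomer", "energy_cm1")
  missing <- setdiff(needed, names(tab))
  if (length(missing))
    stop("site-energy table is missing column(s): ",
         paste(missing, collapse = ", "))
  key <- paste(tab$pigment, tab$monomer, sep = "\r")
  out <- list()
  for (k in unique(key)) {
    g <- tab[key == k, , drop = FALSE]
    g <- g[order(g$time_fs), , drop = FALSE]
    if (nrow(g) < 2L) stop("fewer than 2 samples for pigment ", g$pigment[1],
                           ", monomer ", g$monomer[1])
    dt <- diff(g$time_fs)
    if (max(abs(dt - dt[1])) > 1e-6 * dt[1])
      stop("non-uniform time grid for pigment ", g$pigment[1],
           ", monomer ", g$monomer[1])
    out[[length(out) + 1L]] <- site_energy_trajectory(
      g$pigment[1], g$monomer[1], dt[1], g$energy_cm1)
  }
  out
}

#' Write a site-energy table
#'
#' Inverse of [read_site_energy_table()].
#'
#' @param trajectories List of `site_energy_trajectory` objects.
#' @param path Output CSV file.
#' @return `path`, invisibly.
#' @export
write_site_energy_table <- function(trajectories, path) {
  stopifnot(is.list(trajectories), length(trajectories) >= 1L)
  parts <- lapply(trajectories, function(tr) {
    stopifnot(inherits(tr, "site_energy_trajectory"))
    data.frame(time_fs = (seq_along(tr$energies) - 1L) * tr$time_step,
               pigment = tr$pigment_label, monomer = tr$monomer_label,
               energy_cm1 = tr$energies)
  })
  utils::write.csv(do.call(rbind, parts), path, row.names = FALSE)
  invisible(path)
}

#' Read / write a labeled Hamiltonian matrix as CSV
#'
#' The CSV layout is a square numeric matrix with matching row and column
#' labels (first row and first column). On read the matrix is symmetrized by
#' averaging; asymmetries above 1e-3 cm^-1 trigger a warning.
#'
#' @param path CSV file.
#' @return For `read_hamiltonian_csv`, an `exciton_hamiltonian`.
#' @export
read_hamiltonian_csv <- function(path) {
  .stop_if_empty(path)
  tab <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(tab)
  if (nrow(m) != ncol(m)) stop("Hamiltonian CSV is not square")
  if (!identical(rownames(m), colnames(m)))
    stop("row/column labels of Hamiltonian CSV differ")
  if (!is.numeric(m)) stop("Hamiltonian CSV contains non-numeric entries")
  exciton_hamiltonian(rownames(m), m)
}

#' @rdname read_hamiltonian_csv
#' @param h An `exciton_hamiltonian`.
#' @export
write_hamiltonian_csv <- function(h, path) {
  stopifnot(inherits(h, "exciton_hamiltonian"))
  utils::write.csv(as.data.frame(h$matrix), path, row.names = TRUE)
  invisible(path)
}
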