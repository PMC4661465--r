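#' Coordinate trajectory
#'
#' A sequence of frames sharing one atom label set. Each frame is an
#' n_atoms x 3 matrix in Angstrom with atom labels as row names.
#'
#' @param frames List of labeled n x 3 coordinate matrices.
#' @param frame_times Optional numeric vector of frame times.
#' @return An object of class `coordinate_trajectory`.
#' @export
coordinate_trajectory <- function(frames, frame_times = seq_along(frames)) {
  stopifnot(is.list(frames), length(frames) >= 1L,
            length(frame_times) == length(frames))
  labels <- rownames(frames[[1L]])
  if (is.null(labels)) stop("frames must carry atom labels as row names")
  for (f in frames) {
    stopifnot(is.matrix(f), ncol(f) == 3L)
    if (!identical(rownames(f), labels))
      stop("all frames must share the identical atom label set")
  }
  structure(list(frame_times = as.numeric(frame_times), frames = frames,
                 labels = labels),
            class = "coordinate_trajectory")
}

# Kabsch: optimal proper rotation mapping P onto Q (both centered),
# determinant-corrected to exclude reflections.
.kabsch_rotation <- function(P, Q) {
  H <- t(P) %*% Q
  s <- svd(H)
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' RMSD after optimal rigid-body superposition
#'
#' Superposes `frame` onto `reference` by the closed-form Kabsch
#' (SVD-based, proper-rotation-corrected) least-squares fit on the selected
#' atoms, then reports the RMSD over the selection. With `fit = FALSE` no
#' superposition is applied (plain coordinate RMSD).
#'
#' @param reference,frame Labeled n x 3 coordinate matrices (Angstrom).
#' @param selection Character vector of atom labels; default all labels
#'   common to both.
#' @param fit Superpose before computing the RMSD (default `TRUE`).
#' @return RMSD in Angstrom.
#' @export
superpose_rmsd <- function(reference, frame, selection = NULL, fit = TRUE) {
  stopifnot(is.matrix(reference), is.matrix(frame),
            ncol(reference) == 3L, ncol(frame) == 3L)
  if (is.null(selection))
    selection <- intersect(rownames(reference), rownames(frame))
  if (length(selection) == 0L) stop("empty atom selection")
  if (!all(selection %in% rownames(reference)) ||
      !all(selection %in% rownames(frame)))
    stop("selection contains labels absent from reference or frame")
  R <- reference[selection, , drop = FALSE]
  F <- frame[selection, , drop = FALSE]
  if (fit) {
    if (length(selection) < 3L)
      stop("superposition needs at least 3 selected atoms")
    Rc <- scale(R, scale = FALSE); Fc <- scale(F, scale = FALSE)
    rot <- .kabsch_rotation(Fc, Rc)
    F <- Fc %*% rot
    R <- Rc
  }
  sqrt(mean(rowSums((F - R)^2)))
}

#' Per-frame distances between atom pairs
#'
#' @param traj A `coordinate_trajectory`.
#' @param atom_pairs List of length-2 character vectors of atom labels.
#' @return Numeric matrix, frames x pairs, of Euclidean distances in
#'   Angstrom; columns named `a-b`.
#' @export
distance_series <- function(traj, atom_pairs) {
  stopifnot(inherits(traj, "coordinate_trajectory"), is.list(atom_pairs),
            length(atom_pairs) >= 1L)
  for (p in atom_pairs) {
    if (length(p) != 2L) stop("each atom pair must have exactly 2 labels")
    missing <- setdiff(p, traj$labels)
    if (length(missing))
      stop("atom label(s) not in trajectory: ", paste(missing, collapse = ", "))
  }
  out <- sapply(atom_pairs, function(p) {
    vapply(traj$frames, function(f) sqrt(sum((f[p[1], ] - f[p[2], ])^2)),
           numeric(1))
  })
  out <- matrix(out, nrow = length(traj$frames))
  colnames(out) <- vapply(atom_pairs, paste, character(1), collapse = "-")
  out
}

#' Peak position and FWHM of a Gaussian-like distribution
#'
#' Histograms the values at the given bin width and fits a 3-parameter
#' Gaussian (amplitude, mean, sigma) to bin centers/counts by unweighted
#' least squares; FWHM = 2 sqrt(2 ln 2) sigma. If the fit does not converge
#' the empirical half-maximum crossing width is returned and flagged.
#'
#' @param values Numeric vector (>= 100 values, non-degenerate).
#' @param bin_width Histogram bin width (default 0.01, in the units of
#'   `values`).
#' @return List with `peak_position`, `fwhm` and `method` ("gaussian_fit" or
#'   "half_max_crossing").
#' @export
histogram_fwhm <- function(values, bin_width = 0.01) {
  stopifnot(is.numeric(values), bin_width > 0)
  if (length(values) < 100L) stop("need at least 100 values")
  if (diff(range(values)) < .Machine$double.eps^0.5)
    stop("degenerate (constant) values: distribution has zero width")
  breaks <- seq(min(values) - bin_width, max(values) + bin_width,
                by = bin_width)
  h <- graphics::hist(values, breaks = breaks, plot = FALSE)
  x <- h$mids; y <- h$counts
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ A * exp(-(x - mu)^2 / (2 * s^2)),
      start = list(A = max(y), mu = stats::weighted.mean(x, y),
                   s = max(stats::sd(values), bin_width)),
      lower = c(0, min(x), bin_width / 100)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    p <- stats::coef(fit)
    return(list(peak_position = unname(p["mu"]),
                fwhm = 2 * sqrt(2 * log(2)) * unname(p["s"]),
                method = "gaussian_fit"))
  }
  # fallback: width between half-maximum crossings of the raw histogram
  peak <- which.max(y)
  half <- y[peak] / 2
  left <- x[which(y[seq_len(peak)] >= half)[1]]
  right <- x[peak - 1L + rev(which(y[peak:length(y)] >= half))[1]]
  list(peak_position = x[peak], fwhm = right - left,
       method = "half_max_crossing")
}

#' Read / write a multi-model PDB coordinate trajectory
#'
#' Each PDB MODEL becomes one frame; atom labels are `elety_resno` (e.g.
#' `MG_371`).
#'
#' @param path PDB file.
#' @return For the reader, a `coordinate_trajectory`.
#' @export
read_coordinate_trajectory <- function(path) {
  .stop_if_empty(path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  labels <- paste(pdb$atom$elety, pdb$atom$resno, sep = "_")
  if (anyDuplicated(labels))
    labels <- make.unique(labels, sep = "_")
  frames <- lapply(seq_len(nrow(pdb$xyz)), function(i) {
    m <- matrix(pdb$xyz[i, ], ncol = 3L, byrow = TRUE)
    rownames(m) <- labels
    m
  })
  coordinate_trajectory(frames)
}

#' @rdname read_coordinate_trajectory
#' @param traj A `coordinate_trajectory`. Atom labels of the form
#'   `NAME_resno` are split back into atom name and residue number.
#' @export
write_coordinate_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "coordinate_trajectory"))
  labels <- traj$labels
  parts <- strsplit(labels, "_")
  elety <- vapply(parts, `[`, character(1), 1L)
  resno <- suppressWarnings(as.integer(vapply(parts, function(p)
    if (length(p) >= 2L) p[2L] else NA_character_, character(1))))
  resno[is.na(resno)] <- seq_len(sum(is.na(resno)))
  xyz <- do.call(rbind, lapply(traj$frames, function(f) as.numeric(t(f))))
  bio3d::write.pdb(file = path, xyz = xyz, elety = elety, resno = resno,
                   resid = rep("BCL", length(labels)),
                   chain = rep("A", length(labels)),
                   eleno = seq_along(labels))
  invisible(path)
}
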