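#' Configuration for the Ornstein-Uhlenbeck site-energy generator
#'
#' Defaults emulate the production conditions of the FMO analyses this
#' package targets: 20 ps of site energies sampled every 0.5 fs (40,000
#' samples) at 300 K for each of the three monomers of the trimer, with a
#' reorganization energy of 100 cm^-1, a 15 fs correlation time and a mean
#' site energy of 11450 cm^-1 (mid-range of the eight-site energy ladder).
#'
#' @param lambda_reorg Reorganization energy in cm^-1 (>= 0); sets the
#'   stationary variance 2 lambda k_B T.
#' @param tau_corr Correlation time in fs (> 0).
#' @param temperature Temperature in K (> 0).
#' @param mean_energy Mean site energy in cm^-1.
#' @param time_step Sampling interval in fs (> 0).
#' @param n_steps Number of samples per monomer (>= 2).
#' @param n_monomers Number of independent monomer series (>= 1).
#' @param seed Integer seed.
#' @return An object of class `ou_config`.
#' @export
ou_config <- function(lambda_reorg = 100, tau_corr = 15, temperature = 300,
                      mean_energy = 11450, time_step = 0.5, n_steps = 40000,
                      n_monomers = 3, seed = 1) {
  stopifnot(lambda_reorg >= 0, tau_corr > 0, temperature > 0, time_step > 0,
            n_steps >= 2, n_monomers >= 1)
  structure(list(lambda_reorg = lambda_reorg, tau_corr = tau_corr,
                 temperature = temperature, mean_energy = mean_energy,
                 time_step = time_step, n_steps = as.integer(n_steps),
                 n_monomers = as.integer(n_monomers),
                 seed = as.integer(seed)),
            class = "ou_config")
}

#' Generate Ornstein-Uhlenbeck site-energy trajectories
#'
#' Stationary Gaussian process with exponential autocorrelation, via the
#' exact discretization X_{n+1} = X_n e^{-dt/tau} +
#' sqrt(sigma^2 (1 - e^{-2 dt/tau})) xi_n with stationary variance
#' sigma^2 = 2 lambda k_B T (cm^-2), initialized from the stationary
#' distribution. One independent series per monomer; bit-reproducible for a
#' given (seed, config).
#'
#' @param config An `ou_config`.
#' @param pigment_label Pigment label attached to the output trajectories.
#' @return List of `site_energy_trajectory` objects, one per monomer
#'   (labels "A", "B", ...).
#' @export
generate_ou_site_energies <- function(config, pigment_label = "1") {
  stopifnot(inherits(config, "ou_config"))
  set.seed(config$seed)
  sigma2 <- 2 * config$lambda_reorg * kbt_cm1(config$temperature)
  phi <- exp(-config$time_step / config$tau_corr)
  sd_inn <- sqrt(sigma2 * (1 - phi^2))
  lapply(seq_len(config$n_monomers), function(l) {
    if (sigma2 == 0) {
      x <- rep(0, config$n_steps)
    } else {
      x0 <- stats::rnorm(1, 0, sqrt(sigma2))
      eps <- stats::rnorm(config$n_steps - 1L, 0, sd_inn)
      x <- c(x0, stats::filter(eps, phi, method = "recursive", init = x0))
    }
    site_energy_trajectory(pigment_label, LETTERS[l], config$time_step,
                           config$mean_energy + x)
  })
}

#' Generate a ring of toy pigment geometries
#'
#' Mg positions equally spaced on a circle of the given radius in the z = 0
#' plane; transition dipoles set by the scheme: `"tangential"` (along the
#' local circle tangent), `"parallel"` (all along z), or `"random"` (seeded
#' isotropic unit vectors).
#'
#' @param n Number of pigments (>= 2).
#' @param radius Circle radius in Angstrom (> 0).
#' @param dipole_scheme One of "tangential", "parallel", "random".
#' @param seed Integer seed (used by the random scheme).
#' @param monomer Monomer label for all pigments.
#' @return List of `pigment_geometry` objects labeled "1".."n".
#' @export
generate_pigment_ring <- function(n, radius, dipole_scheme = "tangential",
                                  seed = 1, monomer = "A") {
  stopifnot(n >= 2, radius > 0)
  if (!dipole_scheme %in% c("tangential", "parallel", "random"))
    stop("unknown dipole scheme: ", dipole_scheme)
  set.seed(seed)
  theta <- 2 * pi * (seq_len(n) - 1L) / n
  lapply(seq_len(n), function(i) {
    pos <- radius * c(cos(theta[i]), sin(theta[i]), 0)
    dir <- switch(dipole_scheme,
                  tangential = c(-sin(theta[i]), cos(theta[i]), 0),
                  parallel = c(0, 0, 1),
                  random = { v <- stats::rnorm(3); v / sqrt(sum(v^2)) })
    pigment_geometry(as.character(i), monomer, pos, dir)
  })
}

# uniform random proper rotation from the QR decomposition of a Gaussian
# matrix, sign-fixed and determinant-corrected
.random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

#' Generate a jittered coordinate trajectory
#'
#' Each frame is the base structure plus isotropic per-atom Gaussian jitter
#' of scale `sigma`, optionally followed by a random rigid rotation and
#' translation (which superposition-based statistics must remove).
#'
#' @param base Labeled n x 3 coordinate matrix (Angstrom).
#' @param sigma Jitter scale in Angstrom (>= 0).
#' @param n_frames Number of frames (>= 1).
#' @param rigid_motion Apply a random rigid motion per frame.
#' @param seed Integer seed.
#' @return A `coordinate_trajectory`.
#' @export
generate_jittered_trajectory <- function(base, sigma, n_frames,
                                         rigid_motion = FALSE, seed = 1) {
  stopifnot(is.matrix(base), ncol(base) == 3L, sigma >= 0, n_frames >= 1)
  if (is.null(rownames(base))) stop("base must carry atom labels as row names")
  set.seed(seed)
  frames <- lapply(seq_len(n_frames), function(i) {
    f <- base + matrix(stats::rnorm(length(base), 0, sigma), nrow(base), 3L)
    if (rigid_motion) {
      R <- .random_rotation()
      tr <- stats::runif(3, -5, 5)
      f <- sweep(f %*% t(R), 2L, tr, `+`)
    }
    rownames(f) <- rownames(base)
    f
  })
  coordinate_trajectory(frames)
}
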