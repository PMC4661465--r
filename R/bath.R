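#' Bath correlation function
#'
#' The (classical, real) site-energy autocorrelation function C(t) on a
#' uniform lag grid starting at 0, in cm^-2.
#'
#' @param lags Numeric vector of lags in fs, uniform, starting at 0.
#' @param values Numeric vector of C(t) values in cm^-2.
#' @return An object of class `correlation_function`.
#' @export
correlation_function <- function(lags, values) {
  stopifnot(is.numeric(lags), is.numeric(values), length(lags) == length(values),
            length(lags) >= 2L)
  if (abs(lags[1]) > 1e-12) stop("lags must start at 0")
  dl <- diff(lags)
  if (any(dl <= 0) || max(abs(dl - dl[1])) > 1e-9 * dl[1])
    stop("lags must be strictly increasing and uniform")
  if (values[1] < 0) stop("C(0) must be non-negative")
  structure(list(lags = as.numeric(lags), values = as.numeric(values)),
            class = "correlation_function")
}

#' Fitted bath parameters
#'
#' Parameters of the biexponential decomposition of C(t): a slow component
#' of amplitude `amplitude_slow` and timescale `tau_slow` = 1/gamma, a fast
#' (white-noise-residue-like) component `amplitude_fast`, `tau_fast` =
#' 1/gamma', and the reorganization energy lambda = amplitude_slow /
#' (2 k_B T) from the classical fluctuation-dissipation amplitude mapping.
#'
#' @param lambda_reorg Reorganization energy, cm^-1 (>= 0).
#' @param tau_slow,tau_fast Timescales in fs, `tau_slow > tau_fast > 0`.
#' @param amplitude_slow,amplitude_fast Amplitudes in cm^-2.
#' @param temperature Temperature in K.
#' @return An object of class `bath_parameters`.
#' @export
bath_parameters <- function(lambda_reorg, tau_slow, tau_fast,
                            amplitude_slow, amplitude_fast, temperature) {
  stopifnot(lambda_reorg >= 0, tau_fast > 0, tau_slow > tau_fast,
            temperature > 0)
  structure(list(lambda_reorg = lambda_reorg, tau_slow = tau_slow,
                 tau_fast = tau_fast, amplitude_slow = amplitude_slow,
                 amplitude_fast = amplitude_fast, temperature = temperature),
            class = "bath_parameters")
}

#' @export
print.bath_parameters <- function(x, ...) {
  cat(sprintf("<bath parameters> lambda = %.2f cm^-1, 1/gamma = %.2f fs, 1/gamma' = %.2f fs (T = %g K)\n",
              x$lambda_reorg, x$tau_slow, x$tau_fast, x$temperature))
  invisible(x)
}

#' Site-energy fluctuations
#'
#' Centers a site-energy trajectory on its own mean:
#' dE(t_i) = E(t_i) - <E>.
#'
#' @param traj A `site_energy_trajectory`.
#' @return Numeric vector of fluctuations in cm^-1 (zero mean).
#' @export
fluctuations <- function(traj) {
  stopifnot(inherits(traj, "site_energy_trajectory"))
  traj$energies - mean(traj$energies)
}

#' Site-energy autocorrelation function
#'
#' Biased time-origin-averaged estimator, averaged over monomers:
#' C(t_j) = (1/N_l) sum_l (1/N) sum_i dE_l(t_i + t_j) dE_l(t_i),
#' where the inner sum runs over the N - j admissible origins but is divided
#' by the full length N. C(0) is then the pooled biased variance and the
#' estimate decays smoothly at long lags.
#'
#' @param fluct_series A numeric vector or list of numeric vectors (one
#'   centered series per monomer, equal lengths).
#' @param time_step Sampling interval in fs.
#' @param max_lag Maximum lag in fs; default `min(2000, (N-1)*time_step/2)`.
#' @return A `correlation_function`.
#' @export
autocorrelation <- function(fluct_series, time_step, max_lag = NULL) {
  if (is.numeric(fluct_series)) fluct_series <- list(fluct_series)
  stopifnot(is.list(fluct_series), length(fluct_series) >= 1L,
            is.numeric(time_step), time_step > 0)
  n <- length(fluct_series[[1L]])
  if (n < 2L) stop("series must have at least 2 samples")
  if (!all(vapply(fluct_series, length, integer(1)) == n))
    stop("all monomer series must have the same length")
  if (is.null(max_lag)) max_lag <- min(2000, (n - 1) * time_step / 2)
  if (max_lag > (n - 1) * time_step)
    stop("max_lag exceeds the series duration")
  nlag <- floor(max_lag / time_step + 1e-9)
  acc <- rep(0, nlag + 1L)
  for (x in fluct_series) {
    # type = "covariance", demean = FALSE: sum over origins divided by N,
    # exactly the biased estimator on the pre-centered series
    a <- stats::acf(x, lag.max = nlag, type = "covariance",
                    demean = FALSE, plot = FALSE)
    acc <- acc + as.numeric(a$acf)
  }
  correlation_function(lags = (0:nlag) * time_step,
                       values = acc / length(fluct_series))
}

.biexp_model <- function(t, a, tau1, b, tau2) {
  a * exp(-t / tau1) + b * exp(-t / tau2)
}

#' Fit a biexponential with a fast white-noise-residue component
#'
#' Fits C(t) ~ a exp(-t/tau_slow) + b exp(-t/tau_fast) by least squares and
#' maps the slow amplitude to the reorganization energy via the classical
#' high-temperature relation lambda = a / (2 k_B T), with k_B T in cm^-1.
#' Two modes:
#' \describe{
#'   \item{unconstrained}{4-parameter nonlinear least squares with
#'     multi-start initialization from a log-linear tail fit. If the
#'     biexponential is degenerate (timescales nearly equal, or no
#'     improvement over a single exponential), the single-exponential fit is
#'     returned with a zero fast amplitude.}
#'   \item{constrained}{the fast timescale is fixed at the thermal (first
#'     Matsubara) time hbar beta / (2 pi) (about 4.05 fs at 300 K,
#'     temperature-only dependent); a, tau_slow and b are fitted.}
#' }
#'
#' @param c A `correlation_function` with at least 20 lags and C(0) > 0.
#' @param temperature Temperature in K.
#' @param mode `"unconstrained"` (default) or `"constrained"`.
#' @param n_starts Number of multi-start initializations.
#' @return A `bath_parameters` object.
#' @export
fit_biexponential_wnr <- function(c, temperature,
                                  mode = c("unconstrained", "constrained"),
                                  n_starts = 6) {
  stopifnot(inherits(c, "correlation_function"))
  mode <- match.arg(mode)
  t <- c$lags; y <- c$values
  if (length(t) < 20L) stop("need at least 20 lags to fit")
  if (y[1] <= 0) stop("C(0) must be positive")
  dt <- t[2] - t[1]
  kbt <- kbt_cm1(temperature)
  dat <- data.frame(t = t, y = y)

  # timescale guess from a log-linear fit to the positive early decay
  pos <- which(y > 0.05 * y[1])
  pos <- pos[pos <= max(which(cumsum(y <= 0) == 0), 2L)]
  tau_guess <- if (length(pos) >= 3L) {
    sl <- unname(stats::coef(stats::lm(log(y[pos]) ~ t[pos]))[2])
    if (is.finite(sl) && sl < 0) -1 / sl else max(t) / 5
  } else max(t) / 5

  # Levenberg-Marquardt on the residual function (bounded); info codes 1-3
  # are full convergence, 4 is a marginal stop accepted as a candidate
  try_fit <- function(model, par0, lower) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = par0, fn = function(p) y - model(t, p),
                         lower = lower,
                         control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (is.null(fit) || !fit$info %in% 1:4 || !is.finite(fit$deviance))
      return(NULL)
    fit
  }
  pick_best <- function(fits) {
    fits <- Filter(Negate(is.null), fits)
    if (length(fits) == 0L) return(NULL)
    fits[[which.min(vapply(fits, `[[`, numeric(1), "deviance"))]]
  }

  single <- try_fit(function(t, p) p[1] * exp(-t / p[2]),
                    par0 = c(a = y[1], tau1 = tau_guess),
                    lower = c(0, dt / 10))

  if (mode == "constrained") {
    # thermal (first Matsubara) timescale hbar*beta/(2*pi): ~4.05 fs at 300 K
    hbar_beta <- 1 / (2 * pi * unit_constants()$speed_of_light_cm_fs * kbt)
    tau_fast_fixed <- hbar_beta / (2 * pi)
    model <- function(t, p) p[1] * exp(-t / p[2]) + p[3] * exp(-t / tau_fast_fixed)
    best <- pick_best(lapply(
      unique(c(tau_guess, 2 * tau_guess, max(t) / 4)),
      function(tau1_0) try_fit(model,
                               par0 = c(a = 0.8 * y[1],
                                        tau1 = max(tau1_0, 2 * tau_fast_fixed),
                                        b = 0.2 * y[1]),
                               lower = c(0, 1.01 * tau_fast_fixed, 0))))
    if (is.null(best)) stop("constrained biexponential fit did not converge")
    p <- best$par
    if (tau_fast_fixed < dt)
      warning("fixed fast timescale ", format(tau_fast_fixed),
              " fs is below the sampling interval; reported as bound")
    return(bath_parameters(lambda_reorg = unname(p["a"]) / (2 * kbt),
                           tau_slow = unname(p["tau1"]),
                           tau_fast = tau_fast_fixed,
                           amplitude_slow = unname(p["a"]),
                           amplitude_fast = unname(p["b"]),
                           temperature = temperature))
  }

  # unconstrained: multi-start over fast-timescale initializations
  tau_fast_inits <- unique(pmax(dt, c(4, tau_guess / 4, tau_guess / 10,
                                      seq(dt, tau_guess / 2,
                                          length.out = max(1, n_starts - 3)))))
  model2 <- function(t, p) p[1] * exp(-t / p[2]) + p[3] * exp(-t / p[4])
  best <- pick_best(lapply(
    tau_fast_inits,
    function(tf0) try_fit(model2,
                          par0 = c(a = 0.7 * y[1],
                                   tau1 = max(tau_guess, 2 * tf0),
                                   b = 0.3 * y[1], tau2 = tf0),
                          lower = c(0, dt / 10, 0, dt / 10))))
  if (is.null(best) && is.null(single))
    stop("biexponential fit did not converge from any start")

  use_single <- FALSE
  if (is.null(best)) {
    use_single <- TRUE
  } else {
    p <- best$par
    taus <- sort(c(p["tau1"], p["tau2"]), decreasing = TRUE)
    amps <- c(p["a"], p["b"])[order(c(p["tau1"], p["tau2"]), decreasing = TRUE)]
    # degenerate: equal timescales, a vanishing component, or a weak slow
    # "component" that only chases the statistical noise tail of the
    # estimated C(t). In the white-noise-residue picture the fast component
    # is a residue correction, so a slow mode carrying well under the fast
    # amplitude is spurious.
    degenerate <- taus[2] / taus[1] > 0.5 ||
      min(p["a"], p["b"]) < 1e-6 * y[1] ||
      (amps[1] < 0.2 * amps[2])
    if (!is.null(single) && (degenerate || best$deviance > 0.999 * single$deviance))
      use_single <- TRUE
  }

  if (use_single) {
    if (is.null(single)) stop("single-exponential fallback did not converge")
    p <- single$par
    tau_slow <- unname(p["tau1"]); a <- unname(p["a"])
    b <- 0; tau_fast <- tau_slow / 2
  } else {
    p <- best$par
    if (p["tau1"] >= p["tau2"]) {
      a <- unname(p["a"]); tau_slow <- unname(p["tau1"])
      b <- unname(p["b"]); tau_fast <- unname(p["tau2"])
    } else {
      a <- unname(p["b"]); tau_slow <- unname(p["tau2"])
      b <- unname(p["a"]); tau_fast <- unname(p["tau1"])
    }
  }
  if (tau_fast < dt)
    warning("fitted fast timescale ", format(tau_fast),
            " fs collapsed below the sampling interval; reported as bound")
  bath_parameters(lambda_reorg = a / (2 * kbt),
                  tau_slow = tau_slow, tau_fast = tau_fast,
                  amplitude_slow = a, amplitude_fast = b,
                  temperature = temperature)
}

#' Drude (overdamped Brownian oscillator) spectral density
#'
#' J(omega) = 2 lambda gamma omega / (omega^2 + gamma^2). The maximum lies
#' at omega = gamma where J(gamma) = lambda.
#'
#' @param lambda_reorg Reorganization energy, cm^-1 (>= 0).
#' @param gamma Cutoff frequency, cm^-1 (> 0).
#' @param omega Frequency grid in cm^-1.
#' @return An object of class `spectral_density` (list with `omega`,
#'   `j_values`, both cm^-1).
#' @export
drude_spectral_density <- function(lambda_reorg, gamma, omega) {
  if (!is.numeric(gamma) || gamma <= 0) stop("gamma must be > 0")
  stopifnot(lambda_reorg >= 0, is.numeric(omega))
  j <- 2 * lambda_reorg * gamma * omega / (omega^2 + gamma^2)
  structure(list(omega = as.numeric(omega), j_values = j),
            class = "spectral_density")
}

#' Spectral density from a correlation function
#'
#' Classical fluctuation-dissipation mapping evaluated by trapezoidal
#' quadrature: J(omega) = beta omega_ang Int_0^inf C(t) cos(omega_ang t) dt,
#' with beta = 1/(k_B T) (k_B T in cm^-1) and omega_ang = 2 pi c omega the
#' angular frequency in rad/fs matching the gamma = 1/(2 pi c tau)
#' convention. For C(t) = 2 lambda k_B T exp(-t/tau) this reproduces the
#' Drude form with gamma = 1/(2 pi c tau) exactly.
#'
#' @param c A `correlation_function`.
#' @param temperature Temperature in K.
#' @param omega Frequency grid in cm^-1.
#' @return A `spectral_density`.
#' @export
numerical_spectral_density <- function(c, temperature, omega) {
  stopifnot(inherits(c, "correlation_function"), is.numeric(omega))
  n <- length(c$values)
  if (abs(c$values[n]) > 0.05 * abs(c$values[1]) && c$values[1] > 0)
    warning("correlation function has not decayed below 5% of C(0) by the ",
            "last lag; spectral density may be truncated")
  kbt <- kbt_cm1(temperature)
  cc <- unit_constants()$speed_of_light_cm_fs
  j <- vapply(omega, function(w) {
    w_ang <- 2 * pi * cc * w                       # rad / fs
    integrand <- c$values * cos(w_ang * c$lags)
    (w_ang / kbt) * pracma::trapz(c$lags, integrand)
  }, numeric(1))
  structure(list(omega = as.numeric(omega), j_values = j),
            class = "spectral_density")
}

#' Aggregate per-pigment bath parameters
#'
#' Arithmetic mean of the reorganization energies and of the two timescales;
#' the aggregate cutoff frequency converts the mean slow timescale (not the
#' mean rate): gamma_bar = 1/(2 pi c mean(tau_slow)).
#'
#' @param params Non-empty list of `bath_parameters`.
#' @return List with `mean_lambda` (cm^-1), `mean_tau_slow` (fs),
#'   `cutoff_gamma` (cm^-1), `mean_tau_fast` (fs).
#' @export
aggregate_bath <- function(params) {
  if (!is.list(params) || length(params) == 0L)
    stop("params must be a non-empty list")
  stopifnot(all(vapply(params, inherits, logical(1), "bath_parameters")))
  lam <- vapply(params, `[[`, numeric(1), "lambda_reorg")
  ts <- vapply(params, `[[`, numeric(1), "tau_slow")
  tf <- vapply(params, `[[`, numeric(1), "tau_fast")
  list(mean_lambda = mean(lam),
       mean_tau_slow = mean(ts),
       cutoff_gamma = tau_to_gamma(mean(ts)),
       mean_tau_fast = mean(tf))
}

#' Dimensionless energy-scales convergence parameter
#'
#' Evaluates a dimensionless combination of the bath scales (reorganization
#' energy lambda, cutoff gamma), the average excitonic gap g and the thermal
#' energy, used to locate the environment-assisted transport optimum. The
#' default combination lambda * gamma / (g * k_B T) is a provisional
#' stand-in; any alternative can be plugged in via `formula`.
#'
#' @param lambda_reorg Reorganization energy, cm^-1 (>= 0).
#' @param gamma Cutoff frequency, cm^-1 (> 0).
#' @param gap_g Average excitonic gap, cm^-1 (> 0).
#' @param temperature Temperature in K (> 0).
#' @param formula Optional `function(lambda_reorg, gamma, gap_g, kbt)`
#'   returning the dimensionless value.
#' @return The dimensionless transport parameter.
#' @export
transport_parameter <- function(lambda_reorg, gamma, gap_g, temperature,
                                formula = NULL) {
  stopifnot(lambda_reorg >= 0, gamma > 0, gap_g > 0, temperature > 0)
  kbt <- kbt_cm1(temperature)
  if (is.null(formula))
    return(lambda_reorg * gamma / (gap_g * kbt))
  formula(lambda_reorg, gamma, gap_g, kbt)
}
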