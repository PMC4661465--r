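test_that("fluctuations are centered on the trajectory mean", {
  tr <- site_energy_trajectory("1", "A", 0.5, rep(11450, 10))
  expect_equal(fluctuations(tr), rep(0, 10))

  tr2 <- site_energy_trajectory("1", "A", 0.5, c(11451, 11449))
  expect_equal(fluctuations(tr2), c(1, -1))

  set.seed(3)
  tr3 <- site_energy_trajectory("1", "A", 0.5, rnorm(500, 11450, 100))
  expect_lt(abs(mean(fluctuations(tr3))), 1e-9 * 11450)
})

test_that("autocorrelation matches the direct double-loop estimator", {
  # independent oracle: explicit double loop over time origins, biased norm
  loop_acf <- function(series_list, nlag) {
    n <- length(series_list[[1]])
    vapply(0:nlag, function(j) {
      mean(vapply(series_list, function(x)
        sum(x[seq_len(n - j)] * x[(1 + j):n]) / n, numeric(1)))
    }, numeric(1))
  }

  set.seed(13)
  series <- list(rnorm(40), rnorm(40))
  cf <- autocorrelation(series, time_step = 0.5, max_lag = 10)
  expect_equal(cf$lags, seq(0, 10, by = 0.5))
  expect_equal(cf$values, loop_acf(series, 20), tolerance = 1e-12)

  # alternating series: C(0) = A^2, C(1 step) = -A^2 (N-1)/N
  A <- 3; N <- 24
  alt <- rep(c(A, -A), N / 2)
  cfa <- autocorrelation(alt, 1, max_lag = 2)
  expect_equal(cfa$values[1], A^2)
  expect_equal(cfa$values[2], -A^2 * (N - 1) / N)

  # C(0) is the pooled biased variance, non-negative
  x <- rnorm(100, sd = 30)
  cf0 <- autocorrelation(list(x, 2 * x), 1, max_lag = 5)
  expect_equal(cf0$values[1], (sum(x^2) + sum(4 * x^2)) / 200)

  expect_error(autocorrelation(list(rnorm(10), rnorm(9)), 1, max_lag = 2),
               "same length")
  expect_equal(autocorrelation(rep(0, 50), 1, max_lag = 5)$values,
               rep(0, 6))
})

test_that("biexponential fit recovers exact analytic constructions", {
  kbt <- kbt_cm1(300)
  t <- seq(0, 600, by = 0.5)

  # pure exponential: a = 2 lambda kB T with lambda = 100 cm^-1, tau = 15 fs
  cf <- correlation_function(t, 2 * 100 * kbt * exp(-t / 15))
  bp <- fit_biexponential_wnr(cf, 300)
  expect_equal(bp$lambda_reorg, 100, tolerance = 0.1 / 100)
  expect_equal(bp$tau_slow, 15, tolerance = 0.01 / 15)
  expect_equal(bp$amplitude_fast, 0)

  # exact biexponential, unconstrained mode recovers all parameters within 1%
  a <- 30000; b <- 12000
  cf2 <- correlation_function(t, a * exp(-t / 15) + b * exp(-t / 4))
  bp2 <- fit_biexponential_wnr(cf2, 300)
  expect_equal(bp2$tau_slow, 15, tolerance = 0.01)
  expect_equal(bp2$tau_fast, 4, tolerance = 0.01)
  expect_equal(bp2$amplitude_slow, a, tolerance = 0.01)
  expect_equal(bp2$amplitude_fast, b, tolerance = 0.01)
  expect_equal(bp2$lambda_reorg, a / (2 * kbt), tolerance = 0.01)

  expect_error(fit_biexponential_wnr(
    correlation_function(0:5, exp(-(0:5))), 300), "at least 20")
})

test_that("production-scale OU trajectories are recovered within 10%", {
  cfg <- ou_config(lambda_reorg = 100, tau_corr = 15, seed = 202)
  trs <- generate_ou_site_energies(cfg)
  cf <- autocorrelation(lapply(trs, fluctuations), cfg$time_step)
  bp <- fit_biexponential_wnr(cf, cfg$temperature)
  expect_equal(bp$lambda_reorg, 100, tolerance = 0.1)
  expect_equal(bp$tau_slow, 15, tolerance = 0.1)
})

test_that("Drude spectral density satisfies its algebraic identities", {
  lam <- 102; gam <- 330
  w <- seq(0, 3000, by = 1)
  J <- drude_spectral_density(lam, gam, w)
  expect_equal(J$j_values[1], 0)
  expect_true(all(J$j_values >= 0))
  expect_equal(max(J$j_values), lam, tolerance = 1e-6)
  expect_equal(w[which.max(J$j_values)], gam)
  # J(gamma) = lambda exactly, for any parameter pair
  expect_equal(drude_spectral_density(77, 123, 123)$j_values, 77)
  # omega -> infinity: omega J -> 2 lambda gamma
  expect_equal(1e9 * drude_spectral_density(lam, gam, 1e9)$j_values,
               2 * lam * gam, tolerance = 1e-6)
  expect_equal(drude_spectral_density(0, gam, w)$j_values, rep(0, length(w)))
  expect_error(drude_spectral_density(10, -5, w), "gamma")
})

test_that("numerical spectral density matches the closed form for an exponential bath", {
  kbt <- kbt_cm1(300)
  tau <- 15
  gam <- tau_to_gamma(tau)
  lam <- 100
  t <- seq(0, 3000, by = 0.5)
  cf <- correlation_function(t, 2 * lam * kbt * exp(-t / tau))
  w <- seq(gam / 5, 5 * gam, length.out = 40)
  Jn <- numerical_spectral_density(cf, 300, w)
  Jd <- drude_spectral_density(lam, gam, w)
  expect_lt(max(abs(Jn$j_values / Jd$j_values - 1)), 0.01)

  # linearity: doubling C doubles J
  cf2 <- correlation_function(t, 2 * cf$values)
  expect_equal(numerical_spectral_density(cf2, 300, w)$j_values,
               2 * Jn$j_values, tolerance = 1e-12)

  # zero correlation -> zero spectral density
  cf0 <- correlation_function(t, rep(0, length(t)))
  expect_equal(numerical_spectral_density(cf0, 300, w)$j_values,
               rep(0, length(w)))

  # undecayed correlation functions are flagged
  short <- correlation_function(seq(0, 10, 0.5),
                                2 * lam * kbt * exp(-seq(0, 10, 0.5) / tau))
  expect_warning(numerical_spectral_density(short, 300, w), "decayed")
})

test_that("aggregates reproduce the published per-pigment bath table", {
  agg <- aggregate_bath(fmo_bath_parameters())
  expect_equal(agg$mean_lambda, 101.61, tolerance = 1e-6)
  expect_equal(agg$mean_tau_slow, 16.065, tolerance = 1e-6)
  expect_equal(agg$cutoff_gamma, 330.46, tolerance = 0.01 / 330)
  expect_equal(round(agg$cutoff_gamma), 330)
  expect_equal(agg$mean_tau_fast, 4.19625, tolerance = 1e-6)
  expect_equal(round(agg$mean_tau_fast, 2), 4.2)
  expect_error(aggregate_bath(list()), "non-empty")
})

test_that("transport parameter evaluates the configured combination", {
  expect_equal(transport_parameter(0, 300, 45, 300), 0)
  expect_equal(transport_parameter(100, 300, 45, 300),
               100 * 300 / (45 * kbt_cm1(300)))
  expect_equal(transport_parameter(100, 300, 45, 300,
                                   formula = function(l, g, gp, kbt) 1), 1)
  expect_error(transport_parameter(100, 300, -45, 300))
})

test_that("constrained mode fixes the fast timescale at the thermal time", {
  cfg <- ou_config(n_steps = 20000, seed = 55)
  trs <- generate_ou_site_energies(cfg)
  cf <- autocorrelation(lapply(trs, fluctuations), cfg$time_step)
  bp <- fit_biexponential_wnr(cf, 300, mode = "constrained")
  expect_gt(bp$tau_fast, 3)
  expect_lt(bp$tau_fast, 6)
  expect_gt(bp$tau_slow, bp$tau_fast)
})

test_that("fitted Drude form agrees with the numerical spectral density", {
  cfg <- ou_config(seed = 77)
  trs <- generate_ou_site_energies(cfg)
  fl <- lapply(trs, fluctuations)
  cf <- autocorrelation(fl, cfg$time_step)
  bp <- fit_biexponential_wnr(cf, cfg$temperature)
  # transform a correlation window truncated just past the decay, so the
  # quadrature does not accumulate long-lag estimation noise
  cf_sd <- autocorrelation(fl, cfg$time_step, max_lag = 8 * bp$tau_slow)
  gam <- tau_to_gamma(bp$tau_slow)
  w <- seq(0.8 * gam, 1.2 * gam, length.out = 9)
  Jd <- drude_spectral_density(bp$lambda_reorg, gam, w)
  Jn <- suppressWarnings(numerical_spectral_density(cf_sd, cfg$temperature, w))
  expect_lt(abs(mean(Jn$j_values) / mean(Jd$j_values) - 1), 0.1)
})
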