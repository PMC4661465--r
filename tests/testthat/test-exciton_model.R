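test_that("Hamiltonian assembly validates labels and places energies on the diagonal", {
  h <- fmo_site_hamiltonian()
  expect_equal(sum(diag(h$matrix)), 91674)

  # single pigment, no couplings
  h1 <- build_hamiltonian(c(a = 12000))
  expect_equal(dim(h1$matrix), c(1L, 1L))

  # zero couplings give a diagonal matrix
  V0 <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  hd <- build_hamiltonian(c(a = 1, b = 2, c = 3), V0)
  expect_equal(hd$matrix, diag(c(1, 2, 3)), ignore_attr = TRUE)

  # label mismatch rejected
  expect_error(build_hamiltonian(c(a = 1, x = 2, c = 3), V0), "label")
})

test_that("diagonalization agrees with closed forms", {
  # symmetric 2x2 with zero diagonal: energies +-V, equal-weight excitons
  V <- 37
  h <- exciton_hamiltonian(c("a", "b"),
                           matrix(c(0, V, V, 0), 2, 2,
                                  dimnames = list(c("a", "b"), c("a", "b"))))
  r <- diagonalize(h)
  expect_equal(r$energies_cm1, c(-V, V))
  expect_equal(as.numeric(r$contributions), rep(0.5, 4))

  # n = 3: eigenvalues from the characteristic polynomial solved independently
  set.seed(17)
  m <- matrix(rnorm(9, sd = 50), 3, 3); m <- (m + t(m)) / 2
  diag(m) <- diag(m) + 11000
  labels <- c("a", "b", "c"); dimnames(m) <- list(labels, labels)
  r3 <- diagonalize(exciton_hamiltonian(labels, m))
  # det(m - x I) = -x^3 + tr x^2 - c2 x + det(m)
  c2 <- (sum(diag(m))^2 - sum(m * m)) / 2
  roots <- sort(Re(polyroot(c(det(m), -c2, sum(diag(m)), -1))))
  expect_equal(r3$energies_cm1, roots, tolerance = 1e-5)  # polyroot precision
})

test_that("trace conservation and row normalization hold on random Hamiltonians", {
  set.seed(29)
  for (i in 1:10) {
    n <- sample(2:24, 1)
    m <- matrix(rnorm(n * n, sd = 40), n, n); m <- (m + t(m)) / 2
    diag(m) <- abs(diag(m)) + 11000
    labels <- as.character(seq_len(n))
    dimnames(m) <- list(labels, labels)
    r <- diagonalize(exciton_hamiltonian(labels, m))
    expect_lt(abs(sum(r$energies_cm1) - sum(diag(m))), 1e-6)
    expect_lt(max(abs(rowSums(r$contributions) - 1)), 1e-9)
    expect_lt(max(abs(crossprod(r$eigenvectors) - diag(n))), 1e-9)
  }
})

test_that("the embedded eight-site model reproduces the published decomposition", {
  for (variant in c("prime", "intra")) {
    r <- diagonalize(fmo_site_hamiltonian(variant))
    # energies, highest level first, all within 0.001 eV of print
    expect_lt(max(abs(rev(r$energies_ev) - reference_exciton_energies_ev)),
              0.001)
  }
  # contributions (default 8' coupling variant), all 64 within 0.05
  r <- diagonalize(fmo_site_hamiltonian())
  contrib_desc <- r$contributions[8:1, ]
  expect_lt(max(abs(contrib_desc - reference_exciton_contributions)), 0.05)
})

test_that("snapshot averaging is the element-wise mean", {
  h <- fmo_site_hamiltonian()
  expect_equal(average_hamiltonian(list(h))$matrix, h$matrix)

  set.seed(41)
  snaps <- lapply(1:7, function(i) {
    m <- h$matrix + {d <- matrix(rnorm(64), 8, 8); (d + t(d)) / 2}
    exciton_hamiltonian(h$labels, m)
  })
  manual <- Reduce(`+`, lapply(snaps, `[[`, "matrix")) / 7
  expect_equal(average_hamiltonian(snaps)$matrix, manual)
  expect_error(average_hamiltonian(list()), "non-empty")

  # perturbing up and down by the same matrix recovers the original
  d <- matrix(rnorm(64), 8, 8); d <- (d + t(d)) / 2
  pair <- list(exciton_hamiltonian(h$labels, h$matrix + d),
               exciton_hamiltonian(h$labels, h$matrix - d))
  expect_equal(average_hamiltonian(pair)$matrix, h$matrix)
})

test_that("absorption spectrum: sticks, H-dimer limit and intensity conservation", {
  # single pigment: one stick at the site energy with intensity |mu|^2
  h1 <- build_hamiltonian(c(a = 12000))
  r1 <- diagonalize(h1)
  sp1 <- absorption_spectrum(r1, matrix(c(2, 0, 0), 1, 3), fwhm = 50)
  expect_equal(sp1$stick_energies, 12000)
  expect_equal(sp1$stick_intensities, 4)

  # H-dimer: parallel dipoles, positive coupling -> all intensity on the
  # upper exciton
  V <- 100
  hd <- build_hamiltonian(
    c(a = 12000, b = 12000),
    matrix(c(0, V, V, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b"))))
  rd <- diagonalize(hd)
  mu <- matrix(rep(c(1.5, 0, 0), each = 2), 2, 3)
  spd <- absorption_spectrum(rd, mu, fwhm = 40)
  expect_equal(spd$stick_intensities[1], 0, tolerance = 1e-12)  # lower exciton
  expect_equal(spd$stick_intensities[2], 2 * 1.5^2)             # upper exciton

  # unitary sum rule and quadrature: integrated broadened spectrum equals
  # the stick sum within 0.1% on a wide grid
  set.seed(43)
  r <- diagonalize(fmo_site_hamiltonian())
  dip <- matrix(rnorm(24), 8, 3)
  sp <- absorption_spectrum(r, dip, fwhm = 80)
  expect_equal(sum(sp$stick_intensities), sum(dip^2), tolerance = 1e-9)
  integral <- pracma::trapz(sp$axis, sp$intensity)
  expect_equal(integral, sum(sp$stick_intensities), tolerance = 1e-3)

  expect_error(absorption_spectrum(r, dip[1:3, ]), "n_pigments")
})

test_that("average excitonic gap is the mean adjacent-level spacing", {
  mk <- function(e) {
    labels <- as.character(seq_along(e))
    m <- diag(e, nrow = length(e)); dimnames(m) <- list(labels, labels)
    diagonalize(exciton_hamiltonian(labels, m))
  }
  expect_equal(average_excitonic_gap(mk(c(0, 10, 20))), 10)
  expect_equal(average_excitonic_gap(mk(c(0, 100))), 100)
  expect_error(average_excitonic_gap(mk(42)), "at least 2")

  # the eight-site model: span of ~0.039 eV over 7 gaps, ~45 cm^-1
  g <- average_excitonic_gap(diagonalize(fmo_site_hamiltonian()))
  expect_equal(g, (1.439 - 1.400) * 8065.544 / 7, tolerance = 0.02)
})
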