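test_that("unit constants are positive and conversions round-trip", {
  uc <- unit_constants()
  expect_true(all(unlist(uc) > 0))
  x <- c(0.5, 1.4, 11437)
  expect_lt(max(abs(ev_to_cm1(cm1_to_ev(x)) / x - 1)), 1e-12)
  expect_lt(max(abs(gamma_to_tau(tau_to_gamma(x)) / x - 1)), 1e-12)
  # the adopted angular convention maps the mean slow timescale to ~330 cm^-1
  expect_equal(tau_to_gamma(16.065), 330.4, tolerance = 0.1 / 330.4)
  expect_error(tau_to_gamma(-1))
})

test_that("pigment PDB reader extracts Mg position and the ND->NB dipole", {
  f <- withr::local_tempfile(fileext = ".pdb")
  bio3d::write.pdb(file = f, xyz = matrix(c(1, 1, 1, 0, 0, 0, 0, 0, 2), 1),
                   resno = c(1, 1, 1), chain = rep("A", 3),
                   resid = rep("BCL", 3), elety = c("MG", "ND", "NB"),
                   eleno = 1:3)
  pig <- read_pigments_from_pdb(f)
  expect_length(pig, 1L)
  expect_equal(pig[[1]]$mg_position, c(1, 1, 1))
  expect_equal(pig[[1]]$dipole_direction, c(0, 0, 1))

  # swapping ND and NB flips the dipole
  bio3d::write.pdb(file = f, xyz = matrix(c(1, 1, 1, 0, 0, 0, 0, 0, 2), 1),
                   resno = c(1, 1, 1), chain = rep("A", 3),
                   resid = rep("BCL", 3), elety = c("MG", "NB", "ND"),
                   eleno = 1:3)
  expect_equal(read_pigments_from_pdb(f)[[1]]$dipole_direction, c(0, 0, -1))

  # a pigment residue missing its NB atom is reported by name
  bio3d::write.pdb(file = f, xyz = matrix(c(1, 1, 1, 0, 0, 0), 1),
                   resno = c(7, 7), chain = c("B", "B"),
                   resid = rep("BCL", 2), elety = c("MG", "ND"), eleno = 1:2)
  expect_error(read_pigments_from_pdb(f), "NB")
  expect_error(read_pigments_from_pdb(f), "7")
})

test_that("generator-produced pigment PDB files round-trip", {
  set.seed(42)
  pigments <- random_pigments(8)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pigments_pdb(pigments, f)
  back <- read_pigments_from_pdb(f)
  expect_length(back, 8L)
  for (i in 1:8) {
    expect_equal(back[[i]]$label, pigments[[i]]$label)
    expect_lt(max(abs(back[[i]]$mg_position - pigments[[i]]$mg_position)), 1e-3)
    expect_lt(max(abs(back[[i]]$dipole_direction -
                        pigments[[i]]$dipole_direction)), 2e-3)
  }
  expect_error(read_pigments_from_pdb(withr::local_tempfile(fileext = ".pdb")))
})

test_that("site-energy tables round-trip and validate their grid", {
  tr1 <- site_energy_trajectory("1", "A", 0.5, c(11450, 11460, 11440))
  tr2 <- site_energy_trajectory("1", "B", 0.5, c(11400, 11410, 11395))
  f <- withr::local_tempfile(fileext = ".csv")
  write_site_energy_table(list(tr1, tr2), f)
  back <- read_site_energy_table(f)
  expect_length(back, 2L)
  expect_equal(back[[1]]$energies, tr1$energies)
  expect_equal(back[[2]]$monomer_label, "B")
  expect_equal(back[[1]]$pigment_label, back[[2]]$pigment_label)
  expect_equal(back[[1]]$time_step, 0.5)

  # non-uniform grid rejected
  bad <- data.frame(time_fs = c(0, 0.5, 1.2), pigment = "1", monomer = "A",
                    energy_cm1 = c(1, 2, 3))
  utils::write.csv(bad, f, row.names = FALSE)
  expect_error(read_site_energy_table(f), "non-uniform")

  # missing column rejected
  utils::write.csv(bad[, -4], f, row.names = FALSE)
  expect_error(read_site_energy_table(f), "energy_cm1")

  # empty file rejected with a distinct message
  empty <- withr::local_tempfile(fileext = ".csv")
  file.create(empty)
  expect_error(read_site_energy_table(empty), "empty")
})

test_that("Hamiltonian CSV round-trips, symmetrizes, and validates", {
  h <- fmo_site_hamiltonian()
  f <- withr::local_tempfile(fileext = ".csv")
  write_hamiltonian_csv(h, f)
  back <- read_hamiltonian_csv(f)
  expect_equal(back$labels, h$labels)
  expect_lt(max(abs(back$matrix - h$matrix)), 1e-9)
  expect_equal(unname(back$matrix["3", "3"]), 11332)

  # 1x1 is a valid Hamiltonian
  h1 <- exciton_hamiltonian("x", matrix(12000, 1, 1))
  write_hamiltonian_csv(h1, f)
  expect_equal(read_hamiltonian_csv(f)$matrix[1, 1], 12000,
               ignore_attr = TRUE)

  # asymmetry above 1e-3 is symmetrized with a warning
  m <- matrix(c(10, 1.01, 1.0, 20), 2, 2,
              dimnames = list(c("a", "b"), c("a", "b")))
  utils::write.csv(as.data.frame(m), f, row.names = TRUE)
  expect_warning(hh <- read_hamiltonian_csv(f), "asymmetry")
  expect_equal(unname(hh$matrix["a", "b"]), 1.005)

  # non-square input rejected
  writeLines(c(",a,b", "a,1,2"), f)
  expect_error(read_hamiltonian_csv(f))

  empty <- withr::local_tempfile(fileext = ".csv")
  file.create(empty)
  expect_error(read_hamiltonian_csv(empty), "empty")
})

test_that("random labeled matrices survive a write-read cycle", {
  set.seed(7)
  for (i in 1:5) {
    n <- sample(2:10, 1)
    m <- matrix(rnorm(n * n), n, n)
    m <- (m + t(m)) / 2
    diag(m) <- abs(diag(m)) + 10
    labels <- paste0("p", sample(100, n))
    h <- exciton_hamiltonian(labels, `dimnames<-`(m, list(labels, labels)))
    f <- withr::local_tempfile(fileext = ".csv")
    write_hamiltonian_csv(h, f)
    back <- read_hamiltonian_csv(f)
    expect_equal(back$labels, labels)
    expect_lt(max(abs(back$matrix - h$matrix)), 1e-9)
  }
})
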