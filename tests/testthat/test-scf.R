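test_that("RHF matches the brute-force dense-ERI oracle on H2", {
  h2 <- molecular_system(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 1.4)),
                         unit = "bohr")
  ints <- compute_integrals(h2)
  res <- scf_rhf(ints)
  expect_true(res$converged)
  expect_lt(res$energy, -1.0)
  expect_equal(res$energy, oracle_rhf(ints, 2), tolerance = 1e-9)
})

test_that("SCF density traces count electrons and the energy functional is
           reproducible from the stored matrices", {
  ints <- fixture_ints("water_dimer")
  res <- cached("scf_water_dimer", scf_rhf(ints))
  expect_equal(sum(res$D * ints$S), 20, tolerance = 1e-8)
  # recompute the energy from (h, J, K, h_nuc) independently of the driver
  G <- coulomb_matrix(ints, res$D) - 0.5 * exchange_matrix(ints, res$D)
  E <- sum(ints$h * res$D) + 0.5 * sum(G * res$D) +
    ints$nuclear_repulsion_total
  expect_equal(E, res$energy, tolerance = 1e-10)
  # DIIS transients allowed, final energy below the first iterate
  expect_lte(res$log[length(res$log)], res$log[1])

  he <- compute_integrals(molecular_system("He", matrix(0, 1, 3)))
  rhe <- scf_rhf(he)
  expect_equal(sum(rhe$occ == 2), 1L)
})

test_that("UHF handles one-electron, radical and closed-shell cases", {
  h <- molecular_system("H", matrix(0, 1, 3), multiplicity = 2L)
  ih <- compute_integrals(h)
  u <- scf_uhf(ih)
  # one-electron problem: exact answer by diagonalization
  expect_equal(u$energy, oracle_one_electron(ih), tolerance = 1e-8)
  expect_equal(u$n_alpha - u$n_beta, 1L)
  expect_equal(u$s_squared, 0.75, tolerance = 1e-6)

  ch3 <- molecular_system(
    c("C", "H", "H", "H"),
    rbind(c(0, 0, 0), c(1.079, 0, 0), c(-0.5395, 0.9344, 0),
          c(-0.5395, -0.9344, 0)),
    multiplicity = 2L)
  uc <- scf_uhf(compute_integrals(ch3))
  expect_true(uc$converged)
  expect_equal(uc$n_alpha - uc$n_beta, 1L)

  # variational: UHF ansatz contains RHF
  iw <- fixture_ints("water_dimer")
  expect_lte(scf_uhf(iw)$energy,
             cached("scf_water_dimer", scf_rhf(iw))$energy + 1e-10)
})
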