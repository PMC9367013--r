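test_that("basis expansion and AO counts match the shell definitions", {
  wd <- make_fixture("water_dimer")
  b <- build_basis(wd$system, "sto-3g")
  # minimal basis: O carries 1s,2s,2p (5 AOs), H carries 1s
  expect_equal(b$n_ao, 14L)
  amap <- build_ao_map(b, wd$scheme)
  expect_equal(lengths(amap$fragment_ao), c(7L, 7L))
  expect_equal(sort(unlist(amap$fragment_ao)), 1:14)

  b2 <- build_basis(wd$system, "6-31g")
  expect_equal(b2$n_ao, 26L) # 9 per O + 2 per H, split-valence

  he <- make_fixture("he_pair", r = 5)
  bh <- build_basis(he$system, "sto-3g")
  expect_equal(bh$n_ao, 2L)
  expect_equal(lengths(build_ao_map(bh, he$scheme)$fragment_ao), c(1L, 1L))

  one <- fragment_scheme(wd$system, list(1:6))
  expect_equal(build_ao_map(b, one)$fragment_ao[[1]], 1:14)

  expect_error(build_basis(wd$system, "nope"), "unknown basis")
  na <- molecular_system("Na", matrix(0, 1, 3), charge = 1L)
  expect_error(build_basis(na, "sto-3g"), "not available")
})

test_that("contracted AOs are normalized and overlap is positive definite", {
  for (basis in c("sto-3g", "6-31g")) {
    ints <- fixture_ints("water_dimer", basis)
    expect_equal(diag(ints$S), rep(1, ints$n_ao), tolerance = 1e-10)
    expect_gt(min(eigen(ints$S, symmetric = TRUE)$values), 0)
    expect_equal(ints$S, t(ints$S))
  }
})
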