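test_that("pivoted Cholesky orbitals are local and span-complete", {
  he <- make_fixture("he_pair", r = 100)
  ints <- compute_integrals(he$system, he$scheme)
  scf <- scf_rhf(ints)
  # block-diagonal density: pivots on atom 1 return atom 1's orbital
  c1 <- cholesky_orbitals(scf$D, ints$S, ints$ao_map$fragment_ao[[1]], 1)
  expect_lt(abs(c1[2, 1]), 1e-10)
  # complete factorization rebuilds the density
  call <- cholesky_orbitals(scf$D, ints$S, 1:2, 2)
  expect_lt(max(abs(2 * tcrossprod(call) - scf$D)), 1e-10)
  # requesting more orbitals than the fragment supports fails
  expect_error(cholesky_orbitals(scf$D, ints$S, 1L, 2), "pivot")

  # water dimer: the 5 Cholesky orbitals are more fragment-1-local than the
  # 5 most fragment-1-weighted canonical MOs
  fit <- fixture_fit("water_dimer")
  iw <- fit$ints
  ch <- cholesky_orbitals(fit$scf$D, iw$S, iw$ao_map$fragment_ao[[1]], 5)
  pop_set <- function(C) {
    sum(vapply(seq_len(ncol(C)), function(k) {
      sum((C[, k] * (iw$S %*% C[, k]))[iw$ao_map$fragment_ao[[1]]])
    }, numeric(1)))
  }
  canon <- fit$scf$C[, 1:10]
  pops <- vapply(1:10, function(k) {
    sum((canon[, k] * (iw$S %*% canon[, k]))[iw$ao_map$fragment_ao[[1]]])
  }, numeric(1))
  expect_gt(pop_set(ch), sum(sort(pops, decreasing = TRUE)[1:5]))
})

test_that("localizing a far-separated fragment recovers the isolated atom", {
  fit <- fixture_fit("he_pair", order = NULL, r = 100)
  e_iso <- scf_rhf(compute_integrals(molecular_system("He",
                                                      matrix(0, 1, 3))))$energy
  expect_equal(fit$fragment_energies[1], e_iso, tolerance = 1e-6)
  expect_equal(fit$fragment_energies[2], e_iso, tolerance = 1e-6)
})

test_that("a single-fragment system is left untouched by localization", {
  wd <- make_fixture("water_dimer")
  sch <- fragment_scheme(wd$system, list(1:6))
  fit <- flmo(wd$system, sch)
  expect_equal(fit$fragment_energies[1], fit$scf$energy, tolerance = 1e-10)
  D <- 2 * tcrossprod(fit$orbitals$coeff)
  expect_lt(max(abs(D - fit$scf$D)), 1e-10)
})

test_that("three non-interacting fragments each recover the isolated density", {
  trio <- he_trio(100)
  fit <- flmo(trio$system, trio$scheme)
  iso <- scf_rhf(compute_integrals(molecular_system("He", matrix(0, 1, 3))))
  for (i in 1:3) {
    Di <- fragment_density(fit$orbitals, i)
    idx <- fit$ints$ao_map$fragment_ao[[i]]
    expect_equal(Di[idx, idx, drop = FALSE], unname(iso$D),
                 tolerance = 1e-6)
  }
  rep <- eda(fit, counterpoise = FALSE)
  expect_lt(abs(rep$global$e_int_total), 1e-6)
})

test_that("localization conserves the total density and energy and is
           order-invariant in the totals", {
  for (name in c("water_dimer", "ethane_cut")) {
    for (ord in list(NULL, c(2, 1))) {
      fit <- fixture_fit(name, order = ord)
      expect_lt(fit$density_residual, 1e-10)
      expect_lt(fit$energy_residual, 1e-8)
      C <- fit$orbitals$coeff
      orth <- crossprod(C, fit$ints$S %*% C) - diag(ncol(C))
      expect_lt(max(abs(orth)), 1e-8)
    }
    # totals are invariant under the localization order
    expect_equal(fixture_fit(name)$scf$energy,
                 fixture_fit(name, order = c(2, 1))$scf$energy,
                 tolerance = 1e-10)
  }
})

test_that("greedy fragment-energy traces are non-increasing", {
  for (name in c("water_dimer", "ethane_cut", "hf_dimer")) {
    fit <- fixture_fit(name)
    for (tr in fit$orbitals$traces) {
      if (length(tr) > 1) expect_true(all(diff(tr) <= 1e-12))
    }
  }
})

test_that("re-localizing already-localized orbitals is idempotent", {
  fit <- fixture_fit("water_dimer")
  orb2 <- localize_all(fit$scf, fit$ints, occ = fit$orbitals$coeff)
  expect_lt(abs(sum(orb2$fragment_energies) -
                  sum(fit$orbitals$fragment_energies)), 1e-9)
})

test_that("FLMOs are more fragment-local than canonical MOs", {
  for (name in c("water_dimer", "ethane_cut")) {
    s <- summary(fixture_fit(name))
    expect_gt(s$mean_flmo_fraction, s$mean_canonical_fraction)
  }
  # far-separated fragments: perfectly local orbitals
  he <- fixture_fit("he_pair", r = 100)
  loc <- locality_metrics(he$orbitals, he$ints)
  expect_equal(loc$fraction, rep(1, 2), tolerance = 1e-10)
})

test_that("the ethane cut-bond orbital is shared half-and-half", {
  fit <- fixture_fit("ethane_cut")
  loc <- locality_metrics(fit$orbitals, fit$ints)
  sh <- loc[is.na(fit$orbitals$fragment[loc$orbital]), ]
  expect_equal(nrow(sh), 2L)
  expect_equal(sh$fraction, c(0.5, 0.5), tolerance = 0.1)
})
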