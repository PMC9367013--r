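test_that("nuclear repulsion partitions exactly into fragment and pair terms", {
  he <- make_fixture("he_pair", r = 100)
  ints <- compute_integrals(he$system, he$scheme)
  expect_equal(ints$nuclear_repulsion_pair[1, 2], 4 / 100, tolerance = 1e-14)
  expect_equal(ints$nuclear_repulsion_frag, c(0, 0))

  ints <- fixture_ints("water_dimer")
  Z <- ints$system$Z; R <- ints$system$coords
  direct <- 0
  for (a in 1:5) for (b in (a + 1):6) {
    direct <- direct + Z[a] * Z[b] / sqrt(sum((R[a, ] - R[b, ])^2))
  }
  expect_equal(sum(ints$nuclear_repulsion_frag) +
                 ints$nuclear_repulsion_pair[1, 2], direct,
               tolerance = 1e-12)
  expect_equal(ints$nuclear_repulsion_total, direct, tolerance = 1e-12)
})

test_that("fragment one-electron matrices carry the full kinetic operator", {
  for (name in c("water_dimer", "ethane_cut")) {
    ints <- fixture_ints(name)
    nf <- ints$scheme$n_fragments
    resid <- Reduce(`+`, ints$h_frag) - (nf - 1) * ints$T - ints$h
    expect_lt(max(abs(resid)), 1e-10)
    for (i in seq_len(nf)) expect_equal(ints$V_frag[[i]], t(ints$V_frag[[i]]))
  }
})

test_that("J/K builders are linear and match explicit tensor contractions", {
  ints <- fixture_ints("water_dimer") # 14 AOs
  n <- ints$n_ao
  set.seed(20220727)
  for (rep in 1:5) {
    A <- matrix(rnorm(n * n), n); P <- (A + t(A)) / 2
    expect_lt(max(abs(coulomb_matrix(ints, P) - oracle_J(ints$eri, P))),
              1e-10)
    expect_lt(max(abs(exchange_matrix(ints, P) - oracle_K(ints$eri, P))),
              1e-10)
  }
  A <- matrix(rnorm(n * n), n); P <- (A + t(A)) / 2
  B <- matrix(rnorm(n * n), n); Q <- (B + t(B)) / 2
  expect_equal(coulomb_matrix(ints, 2 * P - 3 * Q),
               2 * coulomb_matrix(ints, P) - 3 * coulomb_matrix(ints, Q),
               tolerance = 1e-10)
  expect_equal(exchange_matrix(ints, 2 * P - 3 * Q),
               2 * exchange_matrix(ints, P) - 3 * exchange_matrix(ints, Q),
               tolerance = 1e-10)
  # Tr[K(P) P] >= 0 for PSD P
  for (rep in 1:3) {
    A <- matrix(rnorm(n * n), n); P <- crossprod(A)
    expect_gte(sum(exchange_matrix(ints, P) * P), 0)
  }
})

test_that("two-electron tensor has the full 8-fold permutation symmetry", {
  ints <- fixture_ints("hf_dimer") # s and p shells on F
  e <- ints$eri
  set.seed(1)
  idx <- matrix(sample(ints$n_ao, 4 * 25, replace = TRUE), ncol = 4)
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; j <- idx[r, 2]; k <- idx[r, 3]; l <- idx[r, 4]
    v <- e[i, j, k, l]
    expect_equal(e[j, i, k, l], v, tolerance = 1e-14)
    expect_equal(e[i, j, l, k], v, tolerance = 1e-14)
    expect_equal(e[k, l, i, j], v, tolerance = 1e-14)
  }
})
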