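test_that("fragment aggregation is a pure partition of the provider total", {
  prov <- synthetic_c6_provider()
  trio <- he_trio(10)
  # single-atom fragments: no intra terms, inter sum equals the total
  dt <- dispersion_partition(trio$system, trio$scheme, provider = prov)
  expect_equal(dt$intra, rep(0, 3))
  expect_equal(sum(dt$pair_energy[upper.tri(dt$pair_energy)]),
               dt$provider_total, tolerance = 1e-12)
  expect_equal(dt$total, dt$provider_total, tolerance = 1e-12)

  wd <- make_fixture("water_dimer")
  dw <- dispersion_partition(wd$system, wd$scheme, provider = prov)
  expect_lt(dw$pair_energy[1, 2], 0)
  expect_equal(sum(dw$intra) + dw$pair_energy[1, 2], dw$provider_total,
               tolerance = 1e-12)

  # permuting fragment labels permutes the table, totals invariant
  sch_swapped <- fragment_scheme(wd$system, list(4:6, 1:3))
  ds <- dispersion_partition(wd$system, sch_swapped, provider = prov)
  expect_equal(ds$pair_energy[1, 2], dw$pair_energy[1, 2], tolerance = 1e-14)
  expect_equal(ds$intra, dw$intra[c(2, 1)], tolerance = 1e-14)
  expect_equal(ds$total, dw$total, tolerance = 1e-14)
})

test_that("far-separated fragments have vanishing dispersion", {
  he <- make_fixture("he_pair", r = 100)
  dt <- dispersion_partition(he$system, he$scheme,
                             provider = synthetic_c6_provider())
  expect_lt(abs(dt$pair_energy[1, 2]), 1e-9)
})

test_that("three-body terms are assigned by fragment membership", {
  trio <- he_trio(10)
  prov3 <- function(symbols, coords) {
    base <- synthetic_c6_provider()(symbols, coords)
    base$threebody <- data.frame(a = 1L, b = 2L, c = 3L, energy = 1e-5)
    base
  }
  # all three atoms in distinct fragments: split equally over the pairs
  dt <- dispersion_partition(trio$system, trio$scheme, provider = prov3)
  base <- dispersion_partition(trio$system, trio$scheme,
                               provider = synthetic_c6_provider())
  expect_equal(dt$pair_energy[1, 2] - base$pair_energy[1, 2], 1e-5 / 3,
               tolerance = 1e-12)
  dd <- dispersion_partition(trio$system, trio$scheme, provider = prov3,
                             three_body = "discard")
  expect_equal(dd$pair_energy, base$pair_energy, tolerance = 1e-14)
  # two atoms sharing a fragment: term goes to that fragment pair
  sch2 <- fragment_scheme(trio$system, list(1:2, 3L))
  d2 <- dispersion_partition(trio$system, sch2, provider = prov3)
  b2 <- dispersion_partition(trio$system, sch2,
                             provider = synthetic_c6_provider())
  expect_equal(d2$pair_energy[1, 2] - b2$pair_energy[1, 2], 1e-5,
               tolerance = 1e-12)
})

test_that("a missing provider disables dispersion with a warning, and the
           report marks it unavailable rather than zero", {
  wd <- make_fixture("water_dimer")
  expect_warning(out <- dispersion_partition(wd$system, wd$scheme, NULL),
                 "provider")
  expect_null(out)
  fit <- fixture_fit("water_dimer")
  rep <- eda(fit, counterpoise = FALSE)
  expect_false(rep$global$dispersion_available)
  expect_true(is.na(rep$pairs$e_disp[1]))
  # with a provider the pair energy enters the totals
  rep2 <- eda(fit, counterpoise = FALSE,
              dispersion = synthetic_c6_provider())
  expect_true(rep2$global$dispersion_available)
  expect_equal(rep2$pairs$e_total[1] - rep$pairs$e_total[1],
               rep2$pairs$e_disp[1], tolerance = 1e-12)
})
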