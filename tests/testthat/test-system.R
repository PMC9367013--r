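test_that("XYZ reading converts Angstrom to Bohr and validates input", {
  f <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("1", "one helium", "He 0 0 0"), f)
  sys <- read_xyz(f)
  expect_equal(length(sys$Z), 1L)
  expect_equal(sys$Z, 2)
  expect_equal(sys$coords, matrix(0, 1, 3))

  writeLines(c("2", "h2", "H 0 0 0", "H 0 0 0.74"), f)
  h2 <- read_xyz(f)
  # 0.74 Angstrom x 1.8897259886 Bohr/Angstrom, computed independently
  expect_equal(sqrt(sum((h2$coords[2, ] - h2$coords[1, ])^2)),
               1.39839723, tolerance = 1e-7)

  writeLines(c("nonsense", "x", "He 0 0 0"), f)
  expect_error(read_xyz(f), "header")
  writeLines(c("1", "bad", "Xx 0 0 0"), f)
  expect_error(read_xyz(f), "unknown element")
  writeLines(c("2", "short", "He 0 0 0"), f)
  expect_error(read_xyz(f), "shorter")
})

test_that("XYZ round trip preserves coordinates to 1e-6 Angstrom", {
  fx <- make_fixture("water_dimer")
  expect_equal(length(fx$system$Z), 6L)
  expect_equal(sum(fx$system$Z), 20)
  f <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(fx$system, f)
  back <- read_xyz(f)
  expect_lt(max(abs(back$coords - fx$system$coords)),
            1e-6 * 1.8897259886)
})

test_that("PDB reader extracts elements, coordinates and residues", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  O   HOH A   1      -1.551  -0.115   0.000  1.00  0.00           O",
    "ATOM      2  H1  HOH A   1      -1.934   0.763   0.000  1.00  0.00           H",
    "ATOM      3  H2  HOH A   1      -0.600   0.041   0.000  1.00  0.00           H",
    "HETATM    4  O   HOH A   2       1.351   0.111   0.000  1.00  0.00           O",
    "END"), f)
  sys <- read_pdb(f)
  expect_equal(sys$symbols, c("O", "H", "H", "O"))
  expect_equal(sys$coords[4, 1] / 1.8897259886, 1.351, tolerance = 1e-6)
  rf <- residue_fragments(sys)
  expect_length(rf, 2L)
  expect_equal(unname(rf[[1]]), 1:3)
})

test_that("fragment electron bookkeeping follows charges and cut bonds", {
  wd <- make_fixture("water_dimer")
  sch <- wd$scheme
  expect_equal(sch$n_doubly, c(5L, 5L))
  expect_equal(sch$n_singly, c(0L, 0L))
  expect_equal(sum(2 * sch$n_doubly + sch$n_singly), 20L)

  et <- make_fixture("ethane_cut")$scheme
  expect_equal(et$n_doubly, c(4L, 4L))
  expect_equal(et$n_singly, c(1L, 1L))
  expect_equal(nrow(et$cut_bonds), 1L)

  sys <- wd$system
  expect_error(fragment_scheme(sys, list(1:4, 3:6)), "overlap")
  expect_error(fragment_scheme(sys, list(1:3, 4:5)), "partition")
  expect_error(fragment_scheme(sys, list(1:3, 4:6), charges = c(1, 0)),
               "charges sum")
  # cut bond inside one fragment is rejected
  expect_error(fragment_scheme(sys, list(1:3, 4:6),
                               cut_bonds = list(c(1, 2))),
               "same fragment")
  # odd electrons per closed fragment without a cut bond
  ion <- molecular_system(sys$symbols, sys$coords, charge = 1L,
                          multiplicity = 2L, unit = "bohr")
  expect_error(fragment_scheme(ion, list(1:3, 4:6), charges = c(1, 0)),
               "even")
})
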