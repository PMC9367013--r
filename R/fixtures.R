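# deterministic geometry builders for the bundled test systems (Angstrom)
.FIXTURE_BUILDERS <- list(
  he_pair = function(r = 5.6) { # r in Bohr
    list(symbols = c("He", "He"),
         coords = rbind(c(0, 0, 0), c(0, 0, r)) / BOHR_PER_ANGSTROM,
         fragments = list(1L, 2L))
  },
  h2_pair = function(r = 6) { # intermolecular separation in Bohr
    d <- 0.74
    list(symbols = rep("H", 4),
         coords = rbind(c(0, 0, 0), c(d, 0, 0),
                        c(0, 0, r / BOHR_PER_ANGSTROM),
                        c(d, 0, r / BOHR_PER_ANGSTROM)),
         fragments = list(1:2, 3:4))
  },
  water_dimer = function() {
    list(symbols = c("O", "H", "H", "O", "H", "H"),
         coords = rbind(
           c(-1.551007, -0.114520, 0.000000),
           c(-1.934259, 0.762503, 0.000000),
           c(-0.599677, 0.040712, 0.000000),
           c(1.350625, 0.111469, 0.000000),
           c(1.680398, -0.373741, -0.758561),
           c(1.680398, -0.373741, 0.758561)),
         fragments = list(1:3, 4:6))
  },
  water_dimer_symmetric = function() {
    w <- rbind(c(0.000000, 0.000000, 1.750000),
               c(0.757200, 0.000000, 2.340000),
               c(-0.757200, 0.000000, 2.340000))
    list(symbols = rep(c("O", "H", "H"), 2),
         coords = rbind(w, -w), # exact inversion symmetry
         fragments = list(1:3, 4:6))
  },
  water_trimer = function() {
    list(symbols = rep(c("O", "H", "H"), 3),
         coords = rbind(
           c(0.000, 0.000, 0.000), c(0.960, 0.000, 0.000),
           c(-0.240, 0.930, 0.000),
           c(2.900, 0.000, 0.000), c(2.420, 0.831, 0.000),
           c(3.570, -0.740, 0.000),
           c(1.450, 2.511, 0.000), c(0.970, 1.680, 0.000),
           c(1.930, 3.251, 0.000)),
         fragments = list(1:3, 4:6, 7:9))
  },
  hf_dimer = function() {
    list(symbols = c("F", "H", "F", "H"),
         coords = rbind(c(0, 0, 0), c(0, 0, 0.92),
                        c(0, 0, 2.72), c(0.893, 0, 2.940)),
         fragments = list(1:2, 3:4))
  },
  ethane_cut = function() {
    list(symbols = c("C", "C", rep("H", 6)),
         coords = rbind(
           c(0.000, 0.000, 0.000), c(0.000, 0.000, 1.536),
           c(1.016, 0.000, -0.394), c(-0.508, 0.880, -0.394),
           c(-0.508, -0.880, -0.394),
           c(0.508, 0.880, 1.930), c(-1.016, 0.000, 1.930),
           c(0.508, -0.880, 1.930)),
         fragments = list(c(1L, 3L, 4L, 5L), c(2L, 6L, 7L, 8L)),
         cut_bonds = list(c(1L, 2L)))
  }
)

#' Bundled deterministic test fixtures
#'
#' Small systems with predefined fragment partitions, used throughout the
#' tests, examples and the invariant suite: `he_pair(r)`, `h2_pair(r)`,
#' `water_dimer` (near-linear hydrogen bond), `water_dimer_symmetric` (exact
#' inversion swap symmetry between the two waters), `water_trimer`,
#' `hf_dimer`, `ethane_cut` (two methyl fragments across the C-C cut bond).
#' Builders are deterministic functions of their parameters.
#'
#' @param name Fixture name; see above.
#' @param ... Geometry parameters (`r` in Bohr for the pair fixtures).
#' @param basis Recommended basis recorded in the fixture.
#' @return An object of class `flmo_fixture`: `name`, `system`
#'   ([molecular_system()]), `scheme` ([fragment_scheme()]), `basis`.
#' @examples
#' make_fixture("he_pair", r = 100)
#' @export
make_fixture <- function(name, ..., basis = "sto-3g") {
  builder <- .FIXTURE_BUILDERS[[name]]
  if (is.null(builder)) {
    stop("unknown fixture '", name, "'; available: ",
         paste(names(.FIXTURE_BUILDERS), collapse = ", "))
  }
  g <- builder(...)
  sys <- molecular_system(g$symbols, g$coords, unit = "angstrom")
  scheme <- fragment_scheme(sys, g$fragments,
                            cut_bonds = if (is.null(g$cut_bonds)) list() else
                              g$cut_bonds)
  structure(list(name = name, system = sys, scheme = scheme, basis = basis),
            class = "flmo_fixture")
}

#' @export
print.flmo_fixture <- function(x, ...) {
  cat("Fixture", x$name, "-", length(x$system$Z), "atoms,",
      x$scheme$n_fragments, "fragments, basis", x$basis, "\n")
  invisible(x)
}

#' @rdname make_fixture
#' @export
fixture_system <- function(name, ...) make_fixture(name, ...)$system

#' List available fixtures
#'
#' @return Character vector of fixture names.
#' @export
available_fixtures <- function() names(.FIXTURE_BUILDERS)

#' Randomly perturb a geometry
#'
#' Displaces every Cartesian coordinate by a uniform draw in
#' `[-magnitude, magnitude]` (Angstrom); used for robustness sweeps such as
#' the exchange-negativity check over distorted hydrogen-bond geometries.
#' Uses the current RNG state; set a seed for reproducibility.
#'
#' @param system A [molecular_system()].
#' @param magnitude Maximum per-coordinate displacement in Angstrom.
#' @return A displaced [molecular_system()].
#' @export
perturb_system <- function(system, magnitude = 0.1) {
  disp <- matrix(stats::runif(3 * length(system$Z), -magnitude, magnitude),
                 ncol = 3) * BOHR_PER_ANGSTROM
  molecular_system(system$symbols, system$coords + disp,
                   charge = system$charge,
                   multiplicity = system$multiplicity, unit = "bohr")
}
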