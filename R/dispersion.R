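#' Partition pairwise dispersion energies over fragment pairs
#'
#' Dispersion is consumed through a pluggable provider (the package does not
#' reimplement dispersion coefficients or damping functions). A provider is a
#' function `function(symbols, coords_bohr)` returning a list with `total`
#' (Hartree), `pairwise` (symmetric n_atoms x n_atoms matrix of atom-pair
#' energies, zero diagonal) and optionally `threebody` (data frame `a`, `b`,
#' `c`, `energy`). Atom-pair energies are aggregated by fragment membership
#' into inter-fragment and intra-fragment contributions, a pure partition of
#' the provider's total.
#'
#' When no provider is available dispersion is disabled with a warning and
#' reported as unavailable rather than zero.
#'
#' @param system A [molecular_system()].
#' @param scheme A [fragment_scheme()].
#' @param provider Provider function, or `NULL`.
#' @param three_body How to assign three-body terms: `"pair2"` assigns a term
#'   to the fragment pair contributing two of its atoms (intra when all three
#'   share a fragment; split equally over the three pairs when all differ);
#'   `"discard"` drops them.
#' @return `NULL` when the provider is missing, otherwise an object of class
#'   `dispersion_table`: `atom_pairwise`, `pair_energy` (n_f x n_f, symmetric,
#'   inter-fragment), `intra` (per fragment), `total`.
#' @export
dispersion_partition <- function(system, scheme, provider = NULL,
                                 three_body = c("pair2", "discard")) {
  three_body <- match.arg(three_body)
  if (is.null(provider)) {
    warning("no dispersion provider available; dispersion disabled")
    return(NULL)
  }
  res <- provider(system$symbols, system$coords)
  pw <- res$pairwise
  n <- length(system$Z)
  stopifnot(is.matrix(pw), nrow(pw) == n, ncol(pw) == n)
  nf <- scheme$n_fragments
  af <- scheme$atom_fragment
  pair_energy <- matrix(0, nf, nf)
  intra <- numeric(nf)
  for (a in seq_len(n - 1)) for (b in (a + 1):n) {
    e <- pw[a, b]
    if (e == 0) next
    fa <- af[a]; fb <- af[b]
    if (fa == fb) intra[fa] <- intra[fa] + e else {
      pair_energy[fa, fb] <- pair_energy[fa, fb] + e
      pair_energy[fb, fa] <- pair_energy[fb, fa] + e
    }
  }
  if (!is.null(res$threebody) && nrow(res$threebody) && three_body == "pair2") {
    for (r in seq_len(nrow(res$threebody))) {
      tb <- res$threebody[r, ]
      fs <- af[c(tb$a, tb$b, tb$c)]
      u <- unique(fs)
      if (length(u) == 1L) {
        intra[u] <- intra[u] + tb$energy
      } else if (length(u) == 2L) {
        maj <- u[c(sum(fs == u[1]), sum(fs == u[2])) == 2][1]
        other <- setdiff(u, maj)
        pair_energy[maj, other] <- pair_energy[maj, other] + tb$energy
        pair_energy[other, maj] <- pair_energy[other, maj] + tb$energy
      } else {
        cmb <- utils::combn(u, 2)
        for (k in seq_len(ncol(cmb))) {
          pair_energy[cmb[1, k], cmb[2, k]] <-
            pair_energy[cmb[1, k], cmb[2, k]] + tb$energy / 3
          pair_energy[cmb[2, k], cmb[1, k]] <-
            pair_energy[cmb[1, k], cmb[2, k]]
        }
      }
    }
  }
  total <- sum(intra) + sum(pair_energy[upper.tri(pair_energy)])
  structure(list(atom_pairwise = pw, pair_energy = pair_energy,
                 intra = intra, total = total,
                 provider_total = res$total),
            class = "dispersion_table")
}

#' Synthetic pairwise dispersion provider (testing only)
#'
#' A deliberately simple damped `-C6 / r^6` pair potential with fixed
#' per-element C6 values. It is a synthetic stand-in used to exercise the
#' fragment-pair partitioning machinery in tests and examples; it is not a
#' parameterized dispersion model and its numbers have no physical standing.
#'
#' @param c6 Named vector of per-element C6 values (Hartree Bohr^6).
#' @param r0 Damping radius (Bohr).
#' @return A provider function for [dispersion_partition()].
#' @export
synthetic_c6_provider <- function(c6 = c(H = 3, He = 1.5, C = 30, N = 22,
                                         O = 15, F = 10),
                                  r0 = 5) {
  function(symbols, coords) {
    n <- length(symbols)
    pw <- matrix(0, n, n)
    if (n > 1) {
      for (a in seq_len(n - 1)) for (b in (a + 1):n) {
        r2 <- sum((coords[a, ] - coords[b, ])^2)
        c6ab <- sqrt(c6[[symbols[a]]] * c6[[symbols[b]]])
        e <- -c6ab / (r2^3 + r0^6)
        pw[a, b] <- pw[b, a] <- e
      }
    }
    list(total = sum(pw[upper.tri(pw)]), pairwise = pw)
  }
}
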