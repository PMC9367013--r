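#' Compute all AO integrals for a fragmented system
#'
#' Produces the full integral set the localizer and the energy decomposition
#' need: overlap `S`, kinetic `T`, per-fragment electron-nuclear attraction
#' `V_frag` (from that fragment's nuclei only), per-fragment one-electron
#' matrices `h_frag = T + V_frag`, the full core Hamiltonian `h`, the nuclear
#' repulsion split into within-fragment and between-fragment parts, the full
#' two-electron tensor and Coulomb/exchange builders `J(P)`, `K(P)` that are
#' linear in an arbitrary symmetric matrix `P`.
#'
#' Every fragment one-electron matrix carries the full kinetic operator, so
#' `sum_i h_frag[[i]] - (N_f - 1) T = h`.
#'
#' @param system A [molecular_system()].
#' @param scheme A [fragment_scheme()]; use a single fragment covering all
#'   atoms for plain calculations.
#' @param basis Basis-set name (see [available_bases()]) or an `ao_basis`.
#' @return An object of class `integral_set`.
#' @export
compute_integrals <- function(system, scheme = NULL, basis = "sto-3g") {
  if (is.null(scheme)) scheme <- .whole_scheme(system)
  if (!inherits(basis, "ao_basis")) basis <- build_basis(system, basis)
  ao_map <- build_ao_map(basis, scheme)
  n <- basis$n_ao
  if (n > 64) {
    stop("integral engine stores the full ERI tensor; systems above 64 AOs ",
         "are out of scope (got ", n, ")")
  }
  ovkin <- .cpp_ov_kin(basis$shells)
  S <- ovkin$S; T_ <- ovkin$T
  ev_min <- min(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < 1e-10) {
    warning("near-linear dependence in the AO basis (min overlap eigenvalue ",
            format(ev_min, digits = 3),
            "); canonical orthogonalization will truncate")
  }
  nuc_kern <- .cpp_nuclear(basis$shells, system$coords)
  nf <- scheme$n_fragments
  V_frag <- vector("list", nf)
  for (i in seq_len(nf)) {
    Vi <- matrix(0, n, n)
    for (k in scheme$fragment_atoms[[i]]) {
      Vi <- Vi - system$Z[k] * nuc_kern[, , k]
    }
    V_frag[[i]] <- Vi
  }
  V_tot <- Reduce(`+`, V_frag)
  h_frag <- lapply(V_frag, function(V) T_ + V)
  h <- T_ + V_tot

  nr <- .nuclear_repulsion_partition(system, scheme)

  eri <- .cpp_eri(basis$shells)
  jmat <- matrix(eri, n * n, n * n)
  kmat <- matrix(aperm(eri, c(1L, 3L, 2L, 4L)), n * n, n * n)

  obj <- list(S = S, T = T_, V_frag = V_frag, h_frag = h_frag, h = h,
              nuclear_repulsion_frag = nr$frag,
              nuclear_repulsion_pair = nr$pair,
              nuclear_repulsion_total = nr$total,
              eri = eri, .jmat = jmat, .kmat = kmat,
              n_ao = n, basis = basis, ao_map = ao_map,
              system = system, scheme = scheme,
              min_overlap_eigenvalue = ev_min)
  class(obj) <- "integral_set"
  obj
}

# within-fragment and between-fragment nuclear repulsion scalars
.nuclear_repulsion_partition <- function(system, scheme) {
  Z <- system$Z; R <- system$coords
  nf <- scheme$n_fragments
  frag <- numeric(nf)
  pair <- matrix(0, nf, nf)
  na <- length(Z)
  if (na > 1) {
    for (a in seq_len(na - 1)) {
      for (b in (a + 1):na) {
        e <- Z[a] * Z[b] / sqrt(sum((R[a, ] - R[b, ])^2))
        fa <- scheme$atom_fragment[a]; fb <- scheme$atom_fragment[b]
        if (fa == fb) {
          frag[fa] <- frag[fa] + e
        } else {
          pair[fa, fb] <- pair[fa, fb] + e
          pair[fb, fa] <- pair[fb, fa] + e
        }
      }
    }
  }
  list(frag = frag, pair = pair, total = sum(frag) + sum(pair) / 2)
}

#' Coulomb matrix J(P)
#'
#' Contraction of the two-electron tensor with an arbitrary symmetric matrix:
#' `J[mu,nu] = sum_{ls} (mu nu | l s) P[l,s]`. Linear in `P`.
#'
#' @param ints An [compute_integrals()] result.
#' @param P Symmetric n_ao x n_ao matrix.
#' @return n_ao x n_ao matrix.
#' @export
coulomb_matrix <- function(ints, P) {
  matrix(ints$.jmat %*% as.vector(P), ints$n_ao, ints$n_ao)
}

#' Exchange matrix K(P)
#'
#' `K[mu,nu] = sum_{ls} (mu l | nu s) P[l,s]`. Linear in `P`.
#'
#' @inheritParams coulomb_matrix
#' @return n_ao x n_ao matrix.
#' @export
exchange_matrix <- function(ints, P) {
  matrix(ints$.kmat %*% as.vector(P), ints$n_ao, ints$n_ao)
}

# closed-shell two-electron matrix G(P) = J(P) - K(P)/2
.gmat <- function(ints, P) {
  coulomb_matrix(ints, P) - 0.5 * exchange_matrix(ints, P)
}

#' @export
print.integral_set <- function(x, ...) {
  cat("Integral set:", x$n_ao, "AOs, basis", x$basis$name, ",",
      x$scheme$n_fragments, "fragment(s)\n")
  invisible(x)
}
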