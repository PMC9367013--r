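# Independent brute-force oracles used across the tests. They deliberately
# avoid the package's matricized J/K builders and DIIS driver: contractions
# are explicit loops/slices over the 4-index tensor, and the SCF below is a
# plain damped Roothaan fixed-point iteration.

oracle_J <- function(eri, P) {
  n <- nrow(P)
  J <- matrix(0, n, n)
  for (mu in seq_len(n)) for (nu in seq_len(n)) {
    J[mu, nu] <- sum(eri[mu, nu, , ] * P)
  }
  J
}

oracle_K <- function(eri, P) {
  n <- nrow(P)
  K <- matrix(0, n, n)
  for (mu in seq_len(n)) for (nu in seq_len(n)) {
    K[mu, nu] <- sum(eri[mu, , nu, ] * P)
  }
  K
}

# dense-ERI restricted HF without DIIS (damped Roothaan); small systems only
oracle_rhf <- function(ints, n_electrons, max_iter = 300, damp = 0.3) {
  S <- ints$S; h <- ints$h
  es <- eigen(S, symmetric = TRUE)
  X <- es$vectors %*% diag(1 / sqrt(es$values), length(es$values))
  nocc <- n_electrons / 2
  dens <- function(F_) {
    Ft <- crossprod(X, F_ %*% X)
    es <- eigen((Ft + t(Ft)) / 2, symmetric = TRUE)
    C <- X %*% es$vectors[, order(es$values), drop = FALSE]
    2 * tcrossprod(C[, seq_len(nocc), drop = FALSE])
  }
  D <- dens(h)
  E_old <- Inf
  for (it in seq_len(max_iter)) {
    G <- oracle_J(ints$eri, D) - 0.5 * oracle_K(ints$eri, D)
    E <- sum(h * D) + 0.5 * sum(G * D) + ints$nuclear_repulsion_total
    D_new <- dens(h + G)
    D <- (1 - damp) * D_new + damp * D
    if (abs(E - E_old) < 1e-12) break
    E_old <- E
  }
  E
}

# single-electron exact ground state: lowest eigenvalue of h in the
# S-orthonormalized basis plus nuclear repulsion
oracle_one_electron <- function(ints) {
  es <- eigen(ints$S, symmetric = TRUE)
  X <- es$vectors %*% diag(1 / sqrt(es$values), length(es$values))
  ht <- crossprod(X, ints$h %*% X)
  min(eigen((ht + t(ht)) / 2, symmetric = TRUE)$values) +
    ints$nuclear_repulsion_total
}

# memoized fits/integral sets so expensive fixtures are built once per run
.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

fixture_fit <- function(name, basis = "sto-3g", order = NULL, ...) {
  key <- paste("fit", name, basis, paste(order, collapse = ""),
               paste(deparse(list(...)), collapse = ""), sep = "_")
  cached(key, {
    fx <- make_fixture(name, ...)
    flmo(fx$system, fx$scheme, basis = basis, order = order)
  })
}

fixture_ints <- function(name, basis = "sto-3g", ...) {
  key <- paste("ints", name, basis,
               paste(deparse(list(...)), collapse = ""), sep = "_")
  cached(key, {
    fx <- make_fixture(name, ...)
    compute_integrals(fx$system, fx$scheme, basis)
  })
}

# three helium atoms far apart (non-interacting limit with 3 fragments)
he_trio <- function(r = 100) {
  sys <- molecular_system(rep("He", 3),
                          rbind(c(0, 0, 0), c(0, 0, r), c(0, r, 0)),
                          unit = "bohr")
  scheme <- fragment_scheme(sys, list(1L, 2L, 3L))
  list(system = sys, scheme = scheme)
}
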