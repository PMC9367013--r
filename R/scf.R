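# canonical orthogonalizer X with eigenvalue cutoff (columns may be dropped
# under near-linear dependence)
.orthogonalizer <- function(S, cutoff = 1e-8) {
  es <- eigen(S, symmetric = TRUE)
  keep <- es$values > cutoff
  es$vectors[, keep, drop = FALSE] %*% diag(1 / sqrt(es$values[keep]),
                                            sum(keep))
}

# Pulay DIIS extrapolation over stored Fock/error pairs
.diis_extrapolate <- function(focks, errs) {
  m <- length(focks)
  B <- matrix(-1, m + 1, m + 1)
  B[m + 1, m + 1] <- 0
  for (i in seq_len(m)) for (j in seq_len(m)) {
    B[i, j] <- sum(errs[[i]] * errs[[j]])
  }
  rhs <- c(numeric(m), -1)
  coef <- tryCatch(solve(B, rhs)[seq_len(m)], error = function(e) NULL)
  if (is.null(coef)) return(focks[[m]])
  F_new <- 0
  for (i in seq_len(m)) F_new <- F_new + coef[i] * focks[[i]]
  F_new
}

#' Restricted Hartree-Fock driver
#'
#' Closed-shell SCF with a core-Hamiltonian initial guess and DIIS
#' convergence acceleration. The one-electron Hamiltonian, nuclear repulsion
#' and electron count can be overridden, which is how counterpoise
#' (full-basis, ghost-center) vacuum calculations are run: the integral set of
#' the full system is reused with `h = ints$h_frag[[i]]` and the fragment's
#' nuclear repulsion and electrons.
#'
#' @param ints An [compute_integrals()] result.
#' @param n_electrons Even electron count (default: the system's).
#' @param h One-electron Hamiltonian (default `ints$h`).
#' @param h_nuc Nuclear repulsion scalar (default: the system total).
#' @param conv_energy,conv_gradient Convergence thresholds on the energy
#'   change (Hartree) and the largest orbital-gradient element `FDS - SDF`.
#' @param max_iter Maximum iterations; non-convergence is flagged, not fatal.
#' @param diis_size DIIS subspace size.
#' @param guess Optional initial density matrix.
#' @return An object of class `scf_result`: `energy`, `converged`, `niter`,
#'   `D`, `C` (all MOs, columns S-orthonormal), `occ`, `mo_energies`,
#'   `log` (per-iteration energies), `grad_max`.
#' @export
scf_rhf <- function(ints, n_electrons = NULL, h = NULL, h_nuc = NULL,
                    conv_energy = 1e-10, conv_gradient = 1e-8,
                    max_iter = 200L, diis_size = 8L, guess = NULL) {
  if (is.null(n_electrons)) n_electrons <- ints$system$n_electrons
  if (n_electrons %% 2L != 0L) {
    stop("restricted HF needs an even electron count; use scf_uhf")
  }
  if (is.null(h)) h <- ints$h
  if (is.null(h_nuc)) h_nuc <- ints$nuclear_repulsion_total
  S <- ints$S
  X <- .orthogonalizer(S)
  nocc <- n_electrons %/% 2L

  mo_from_fock <- function(F_) {
    Ft <- crossprod(X, F_ %*% X)
    es <- eigen((Ft + t(Ft)) / 2, symmetric = TRUE)
    ord <- order(es$values)
    list(C = X %*% es$vectors[, ord, drop = FALSE], e = es$values[ord])
  }
  density <- function(C) {
    if (nocc == 0) return(matrix(0, nrow(S), nrow(S)))
    2 * tcrossprod(C[, seq_len(nocc), drop = FALSE])
  }
  energy_of <- function(D) sum(h * D) + 0.5 * sum(.gmat(ints, D) * D) + h_nuc

  if (is.null(guess)) {
    D <- density(mo_from_fock(h)$C)
  } else D <- guess
  focks <- list(); errs <- list()
  E_old <- Inf; log_e <- numeric(0); converged <- FALSE
  C <- NULL; moe <- NULL; grad_max <- NA_real_
  for (it in seq_len(max_iter)) {
    F_ <- h + .gmat(ints, D)
    err <- crossprod(X, (F_ %*% D %*% S - S %*% D %*% F_) %*% X)
    grad_max <- max(abs(err))
    focks <- c(focks, list(F_)); errs <- c(errs, list(err))
    if (length(focks) > diis_size) {
      focks <- focks[-1]; errs <- errs[-1]
    }
    F_use <- if (length(focks) > 1) .diis_extrapolate(focks, errs) else F_
    mo <- mo_from_fock(F_use)
    C <- mo$C; moe <- mo$e
    D <- density(C)
    E <- energy_of(D)
    log_e <- c(log_e, E)
    if (abs(E - E_old) < conv_energy && grad_max < conv_gradient) {
      converged <- TRUE
      break
    }
    E_old <- E
  }
  if (!converged) {
    warning("RHF did not converge in ", max_iter, " iterations (dE = ",
            format(if (length(log_e) > 1) diff(tail(log_e, 2)) else NA), ")")
  }
  structure(list(energy = log_e[length(log_e)], converged = converged,
                 niter = length(log_e), D = D, C = C,
                 occ = c(rep(2, nocc), rep(0, ncol(C) - nocc)),
                 mo_energies = moe, log = log_e, grad_max = grad_max,
                 n_electrons = n_electrons, kind = "rhf"),
            class = "scf_result")
}

#' Unrestricted Hartree-Fock driver
#'
#' Open-shell SCF with separate alpha/beta orbital sets; used for vacuum
#' calculations of open-shell (cut-bond) fragments. Reports the S^2
#' expectation value.
#'
#' @inheritParams scf_rhf
#' @param n_electrons Electron count (default: the system's).
#' @param multiplicity Spin multiplicity 2S+1 (default: the system's).
#' @return An `scf_result` with additional `Da`, `Db`, `Ca`, `Cb`,
#'   `n_alpha`, `n_beta` and `s_squared`.
#' @export
scf_uhf <- function(ints, n_electrons = NULL, multiplicity = NULL,
                    h = NULL, h_nuc = NULL,
                    conv_energy = 1e-10, conv_gradient = 1e-8,
                    max_iter = 200L, diis_size = 8L) {
  if (is.null(n_electrons)) n_electrons <- ints$system$n_electrons
  if (is.null(multiplicity)) multiplicity <- ints$system$multiplicity
  if (is.null(h)) h <- ints$h
  if (is.null(h_nuc)) h_nuc <- ints$nuclear_repulsion_total
  n_open <- multiplicity - 1L
  if ((n_electrons - n_open) %% 2L != 0L || n_electrons < n_open) {
    stop("inconsistent electron count / multiplicity")
  }
  na <- (n_electrons + n_open) %/% 2L
  nb <- (n_electrons - n_open) %/% 2L
  S <- ints$S
  X <- .orthogonalizer(S)

  mo_from_fock <- function(F_) {
    Ft <- crossprod(X, F_ %*% X)
    es <- eigen((Ft + t(Ft)) / 2, symmetric = TRUE)
    ord <- order(es$values)
    list(C = X %*% es$vectors[, ord, drop = FALSE], e = es$values[ord])
  }
  dens <- function(C, nocc) {
    if (nocc == 0) return(matrix(0, nrow(S), nrow(S)))
    tcrossprod(C[, seq_len(nocc), drop = FALSE])
  }

  mo0 <- mo_from_fock(h)
  Ca <- Cb <- mo0$C
  Da <- dens(Ca, na); Db <- dens(Cb, nb)
  focks <- list(); errs <- list()
  E_old <- Inf; log_e <- numeric(0); converged <- FALSE
  ea <- eb <- NULL; grad_max <- NA_real_
  for (it in seq_len(max_iter)) {
    Dt <- Da + Db
    Jt <- coulomb_matrix(ints, Dt)
    Fa <- h + Jt - exchange_matrix(ints, Da)
    Fb <- h + Jt - exchange_matrix(ints, Db)
    erra <- crossprod(X, (Fa %*% Da %*% S - S %*% Da %*% Fa) %*% X)
    errb <- crossprod(X, (Fb %*% Db %*% S - S %*% Db %*% Fb) %*% X)
    grad_max <- max(abs(erra), abs(errb))
    focks <- c(focks, list(list(Fa, Fb)))
    errs <- c(errs, list(rbind(erra, errb)))
    if (length(focks) > diis_size) { focks <- focks[-1]; errs <- errs[-1] }
    if (length(focks) > 1) {
      m <- length(focks)
      B <- matrix(-1, m + 1, m + 1); B[m + 1, m + 1] <- 0
      for (i in seq_len(m)) for (j in seq_len(m)) {
        B[i, j] <- sum(errs[[i]] * errs[[j]])
      }
      coef <- tryCatch(solve(B, c(numeric(m), -1))[seq_len(m)],
                       error = function(e) NULL)
      if (!is.null(coef)) {
        Fa <- Reduce(`+`, Map(function(f, c) c * f[[1]], focks, coef))
        Fb <- Reduce(`+`, Map(function(f, c) c * f[[2]], focks, coef))
      }
    }
    moa <- mo_from_fock(Fa); mob <- mo_from_fock(Fb)
    Ca <- moa$C; Cb <- mob$C; ea <- moa$e; eb <- mob$e
    Da <- dens(Ca, na); Db <- dens(Cb, nb)
    Dt <- Da + Db
    Jt <- coulomb_matrix(ints, Dt)
    Ka <- exchange_matrix(ints, Da); Kb <- exchange_matrix(ints, Db)
    E <- sum(h * Dt) + 0.5 * (sum(Jt * Dt) - sum(Ka * Da) - sum(Kb * Db)) +
      h_nuc
    log_e <- c(log_e, E)
    if (abs(E - E_old) < conv_energy && grad_max < conv_gradient) {
      converged <- TRUE
      break
    }
    E_old <- E
  }
  if (!converged) {
    warning("UHF did not converge in ", max_iter, " iterations")
  }
  # <S^2> = Sz(Sz+1) + Nb - sum |<a_i|S|b_j>|^2
  sz <- n_open / 2
  s2 <- sz * (sz + 1) + nb
  if (na > 0 && nb > 0) {
    ov <- crossprod(Ca[, seq_len(na), drop = FALSE],
                    S %*% Cb[, seq_len(nb), drop = FALSE])
    s2 <- s2 - sum(ov^2)
  }
  structure(list(energy = log_e[length(log_e)], converged = converged,
                 niter = length(log_e), D = Da + Db, Da = Da, Db = Db,
                 Ca = Ca, Cb = Cb, mo_energies_alpha = ea,
                 mo_energies_beta = eb, n_alpha = na, n_beta = nb,
                 s_squared = s2, log = log_e, grad_max = grad_max,
                 n_electrons = n_electrons, kind = "uhf"),
            class = "scf_result")
}

#' @export
print.scf_result <- function(x, ...) {
  cat(sprintf("%s energy: %.10f Hartree (%s in %d iterations)\n",
              toupper(x$kind), x$energy,
              if (x$converged) "converged" else "NOT converged", x$niter))
  invisible(x)
}
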