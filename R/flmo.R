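# Mulliken population of an S-normalised orbital c on a set of AOs
.mulliken_pop <- function(c_, S, ao_idx) {
  sum((c_ * (S %*% c_))[ao_idx])
}

#' Pivoted-Cholesky fragment orbitals
#'
#' Partial pivoted Cholesky factorization of half the density matrix with
#' pivots restricted to one fragment's AO indices, stopped after `n_orbitals`
#' vectors, followed by symmetric Loewdin orthonormalization in the S metric.
#' The returned orbitals are inherently local to the pivot AOs and lie in the
#' span of the occupied space of `D`; they are the starting guess of each
#' localization step.
#'
#' @param D Symmetric positive-semidefinite density matrix (occupation 2
#'   convention: the factored matrix is `D / 2`).
#' @param S AO overlap matrix.
#' @param ao_indices AO indices allowed as pivots (typically one fragment's).
#' @param n_orbitals Number of orbitals to extract.
#' @param tol Pivot breakdown threshold.
#' @return n_ao x n_orbitals coefficient matrix, S-orthonormal.
#' @export
cholesky_orbitals <- function(D, S, ao_indices, n_orbitals, tol = 1e-10) {
  M <- D / 2
  n <- nrow(M)
  if (n_orbitals < 1) stop("n_orbitals must be positive")
  L <- matrix(0, n, n_orbitals)
  d <- diag(M)
  allowed <- as.integer(ao_indices)
  for (k in seq_len(n_orbitals)) {
    if (length(allowed) == 0L) stop("pivot pool exhausted")
    q <- allowed[which.max(d[allowed])]
    if (d[q] < tol) {
      stop("Cholesky pivot ", format(d[q], digits = 3), " below ", tol,
           " after ", k - 1, " orbitals: the fragment AOs cannot support ",
           n_orbitals, " orbitals")
    }
    col <- M[, q]
    if (k > 1) {
      col <- col - L[, seq_len(k - 1), drop = FALSE] %*% L[q, seq_len(k - 1)]
    }
    L[, k] <- col / sqrt(d[q])
    d <- d - L[, k]^2
    allowed <- setdiff(allowed, q)
  }
  # Loewdin S-orthonormalization within the extracted set
  O <- crossprod(L, S %*% L)
  es <- eigen((O + t(O)) / 2, symmetric = TRUE)
  if (min(es$values) < 1e-12) stop("Cholesky orbitals are linearly dependent")
  L %*% es$vectors %*% diag(1 / sqrt(es$values), n_orbitals) %*% t(es$vectors)
}

# fragment energy functional E^i(D^i) = Tr[h_i D] + 1/2 Tr[G(D) D] + hnuc_i
.fragment_energy <- function(ints, i, Di) {
  sum(ints$h_frag[[i]] * Di) + 0.5 * sum(.gmat(ints, Di) * Di) +
    ints$nuclear_repulsion_frag[i]
}

# Extract the cut-bond shared orbital from the S-orthonormal span B: the
# span orbital maximizing the product of Mulliken populations on the two
# bonded atoms. A shared sigma orbital scores ~0.25 while orbitals localized
# on either atom alone score ~0, so the product uniquely singles out the bond
# orbital (a plain joint population cannot: a one-atom core orbital and the
# bond orbital both carry a joint population near 1). Solved by a small
# fixed-point iteration on the product's stationarity condition.
.extract_bond_orbital <- function(B, bond, ints) {
  S <- ints$S
  mull_op <- function(atom) {
    Ia <- ints$basis$ao_atom == atom
    M <- S * 0
    M[Ia, ] <- S[Ia, ]
    Mp <- (M + t(M)) / 2
    crossprod(B, Mp %*% B)
  }
  A <- mull_op(bond$atom_a)
  Bm <- mull_op(bond$atom_b)
  m <- ncol(B)
  score <- function(u) {
    (sum(u * (A %*% u))) * (sum(u * (Bm %*% u)))
  }
  # candidates: eigenvectors of the joint population operator
  es <- eigen(A + Bm, symmetric = TRUE)
  cand <- es$vectors[, order(-es$values)[seq_len(min(4, m))], drop = FALSE]
  u <- cand[, which.max(apply(cand, 2, score))]
  best <- u; best_f <- score(u)
  for (it in seq_len(60)) {
    qa <- sum(u * (A %*% u)); qb <- sum(u * (Bm %*% u))
    G <- qb * A + qa * Bm # gradient operator of the product
    eg <- eigen(G, symmetric = TRUE)
    u_new <- eg$vectors[, which.max(eg$values)]
    if (sum(u_new * u) < 0) u_new <- -u_new
    f_new <- score(u_new)
    if (f_new > best_f) { best <- u_new; best_f <- f_new }
    if (max(abs(u_new - u)) < 1e-12) break
    u <- u_new
  }
  best
}

# S-orthogonal complement of coordinate vectors `keep` (orthonormal columns)
# within the span B; deterministic via eigenvectors of the projector
.span_complement <- function(B, keep) {
  m <- ncol(B)
  P <- diag(m) - tcrossprod(keep)
  es <- eigen((P + t(P)) / 2, symmetric = TRUE)
  nkeep <- m - ncol(keep)
  B %*% es$vectors[, order(-es$values)[seq_len(nkeep)], drop = FALSE]
}

# One localization step: select fragment i's occupied orbitals from the
# remaining S-orthonormal span B by a projected Roothaan iteration on
# F^i = h_i + G(D^i), with a monotonicity safeguard (level shift escalation
# on any uphill step). Pending cut-bond shared orbitals are extracted first
# by the population-product criterion and held fixed during the iteration.
.localize_one <- function(B, i, ints, scheme, shared_fixed, pending_bonds,
                          conv = 1e-9, max_iter = 100L, level_shift = 0.2) {
  S <- ints$S
  nd <- scheme$n_doubly[i]
  np <- nrow(pending_bonds)
  m <- ncol(B)
  if (m < nd + np) {
    stop("remaining occupied span (", m, ") smaller than fragment ", i,
         " orbital count (", nd + np, ")")
  }
  frag_ao <- ints$ao_map$fragment_ao[[i]]

  # extract pending shared orbitals, removing each from the working span
  Cs <- NULL
  if (np > 0) {
    Cs <- matrix(0, nrow(B), np)
    for (bi in seq_len(np)) {
      u <- .extract_bond_orbital(B, pending_bonds[bi, ], ints)
      Cs[, bi] <- B %*% u
      B <- .span_complement(B, matrix(u, ncol = 1))
    }
    m <- ncol(B)
  }

  D_fixed <- matrix(0, nrow(B), nrow(B))
  if (length(shared_fixed)) {
    for (cs in shared_fixed) D_fixed <- D_fixed + tcrossprod(cs)
  }
  if (np > 0) D_fixed <- D_fixed + tcrossprod(Cs)

  # aufbau selection; degenerate ties broken by larger own-fragment
  # population, then index
  select_cols <- function(U, ev) {
    pool <- seq_len(ncol(U))
    ord <- order(ev)
    sel_d <- ord[seq_len(nd)]
    if (nd > 0 && length(pool) > nd) {
      lowest <- sort(ev)[nd]
      degen <- pool[abs(ev - lowest) < 1e-10]
      if (length(degen) > 1) {
        C_deg <- B %*% U[, degen, drop = FALSE]
        own <- vapply(seq_along(degen), function(k) {
          .mulliken_pop(C_deg[, k], S, frag_ao)
        }, numeric(1))
        sure <- pool[ev < lowest - 1e-10]
        fill <- degen[order(-own, degen)][seq_len(nd - length(sure))]
        sel_d <- c(sure, fill)
      }
    }
    sel_d
  }

  build_D <- function(U, sel) {
    Cd <- B %*% U[, sel, drop = FALSE]
    list(Cd = Cd, Di = 2 * tcrossprod(Cd) + D_fixed)
  }

  # starting guess: partial Cholesky of the remaining density
  if (nd > 0) {
    D_rem <- 2 * tcrossprod(B)
    C0 <- cholesky_orbitals(D_rem, S, frag_ao, nd)
    U <- crossprod(B, S %*% C0) # coords in the remaining basis, orthonormal
  } else {
    U <- matrix(0, m, 0)
  }
  sel <- seq_len(nd)
  cur <- build_D(U, sel)
  E_cur <- .fragment_energy(ints, i, cur$Di)
  trace <- E_cur
  converged <- nd == 0
  V_last <- U; sel_last <- sel
  Idm <- diag(m)
  P_occ <- tcrossprod(U[, sel, drop = FALSE])
  if (!converged) for (it in seq_len(max_iter)) {
    F_ <- ints$h_frag[[i]] + .gmat(ints, cur$Di)
    Ft0 <- crossprod(B, F_ %*% B)
    Ft0 <- (Ft0 + t(Ft0)) / 2
    shift <- 0
    repeat {
      Ft <- if (shift > 0) Ft0 + shift * (Idm - P_occ) else Ft0
      es <- eigen(Ft, symmetric = TRUE)
      V <- es$vectors; ev <- es$values
      sel_new <- select_cols(V, ev)
      new <- build_D(V, sel_new)
      E_new <- .fragment_energy(ints, i, new$Di)
      if (E_new <= E_cur + 1e-12 || shift > 52) break
      shift <- if (shift == 0) level_shift else 2 * shift
    }
    trace <- c(trace, E_new)
    V_last <- V; sel_last <- sel_new
    P_occ <- tcrossprod(V[, sel_new, drop = FALSE])
    dE <- E_new - E_cur
    cur <- new; E_cur <- E_new
    if (abs(dE) < conv) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("fragment ", i, " localization not converged in ", max_iter,
            " iterations (last dE = ",
            format(diff(tail(trace, 2)), digits = 3), "); best iterate kept")
  }
  B_new <- if (nd > 0) {
    .span_complement(B, V_last[, sel_last, drop = FALSE])
  } else B
  list(Cd = cur$Cd, Cs = Cs, B = B_new, trace = trace,
       converged = converged, energy = E_cur)
}

#' Sequential fragment localization of the occupied space
#'
#' Runs the `N_f - 1` occupied-subspace SCF steps that turn canonical occupied
#' orbitals into fragment localized molecular orbitals (FLMOs): at each step
#' one fragment's orbitals are variationally selected from the remaining
#' occupied span by minimizing that fragment's energy functional, then removed
#' from the span; the last fragment inherits the final remaining span without
#' optimization. The total density is conserved at every step.
#'
#' Cut-bond shared orbitals are extracted once (at the first incident
#' fragment's step, chosen as the span orbital with maximal joint Mulliken
#' population on the two bonded atoms) and referenced by both incident
#' fragments with occupation 1 each.
#'
#' @param scf A converged [scf_rhf()] result for the full system.
#' @param ints The matching [compute_integrals()] result.
#' @param order Fragment permutation giving the localization order (default:
#'   input order).
#' @param occ Optional n_ao x n_occ S-orthonormal matrix to use as the
#'   occupied span instead of the canonical occupied orbitals (e.g. to re-run
#'   the localization on already-localized orbitals).
#' @param conv Convergence threshold on the per-step fragment energy change
#'   (Hartree).
#' @param max_iter Maximum iterations per fragment.
#' @return An object of class `flmo_orbitals`: `coeff` (n_ao x n_occ, each
#'   stored once with total occupation 2), `fragment` (tag per orbital, `NA`
#'   for shared), `shared` (data frame bond/orbital bookkeeping),
#'   `fragment_orbitals` (per fragment: doubly and shared column indices),
#'   `traces` (per-step energy traces), `fragment_energies`, `order`.
#' @export
localize_all <- function(scf, ints, order = NULL, occ = NULL,
                         conv = 1e-9, max_iter = 100L) {
  scheme <- ints$scheme
  nf <- scheme$n_fragments
  if (is.null(order)) order <- seq_len(nf)
  order <- as.integer(order)
  if (!identical(sort(order), seq_len(nf))) {
    stop("'order' must be a permutation of 1..", nf)
  }
  nocc <- ints$system$n_electrons %/% 2L
  if (is.null(occ)) {
    if (!isTRUE(scf$converged)) {
      warning("reference SCF is not converged; localization proceeds anyway")
    }
    occ <- scf$C[, seq_len(nocc), drop = FALSE]
  }
  stopifnot(ncol(occ) == nocc)

  cb <- scheme$cut_bonds
  shared_coeff <- vector("list", nrow(cb)) # filled when extracted
  doubly <- vector("list", nf)
  traces <- vector("list", nf)
  conv_flags <- rep(NA, nf)
  B <- occ

  for (k in seq_len(nf)) {
    i <- order[k]
    incident <- which(cb$fragment_a == i | cb$fragment_b == i)
    pend_idx <- incident[vapply(shared_coeff[incident], is.null, TRUE)]
    fixed <- shared_coeff[setdiff(incident, pend_idx)]
    if (k < nf) {
      res <- .localize_one(B, i, ints, scheme, fixed,
                           cb[pend_idx, , drop = FALSE],
                           conv = conv, max_iter = max_iter)
      doubly[[i]] <- res$Cd
      if (length(pend_idx)) {
        for (b in seq_along(pend_idx)) {
          shared_coeff[[pend_idx[b]]] <- res$Cs[, b]
        }
      }
      B <- res$B
      traces[[i]] <- res$trace
      conv_flags[i] <- res$converged
    } else {
      # last fragment inherits the remaining span
      if (length(pend_idx)) {
        stop("internal error: unextracted shared orbitals at the last step")
      }
      if (ncol(B) != scheme$n_doubly[i]) {
        stop("remaining span (", ncol(B), ") does not match last fragment's ",
             "doubly occupied count (", scheme$n_doubly[i], ")")
      }
      doubly[[i]] <- B
      Di <- 2 * tcrossprod(B)
      for (cs in shared_coeff[incident]) Di <- Di + tcrossprod(cs)
      traces[[i]] <- .fragment_energy(ints, i, Di)
      conv_flags[i] <- TRUE
    }
  }

  coeff <- do.call(cbind, c(doubly, shared_coeff))
  tags <- c(rep(seq_len(nf), vapply(doubly, ncol, 1L)),
            rep(NA_integer_, nrow(cb)))
  shared_tbl <- cb
  if (nrow(cb)) {
    shared_tbl$orbital <- sum(vapply(doubly, ncol, 1L)) + seq_len(nrow(cb))
  } else shared_tbl$orbital <- integer(0)

  frag_orbitals <- lapply(seq_len(nf), function(i) {
    list(doubly = which(tags == i),
         shared = shared_tbl$orbital[shared_tbl$fragment_a == i |
                                       shared_tbl$fragment_b == i])
  })
  fe <- vapply(seq_len(nf), function(i) {
    tr <- traces[[i]]
    tr[length(tr)]
  }, numeric(1))

  structure(list(coeff = coeff, occupation = rep(2, ncol(coeff)),
                 fragment = tags, shared = shared_tbl,
                 fragment_orbitals = frag_orbitals, traces = traces,
                 fragment_energies = fe, order = order,
                 converged = conv_flags),
            class = "flmo_orbitals")
}

#' Fragment density matrix from FLMOs
#'
#' Builds `D^i` from fragment `i`'s doubly occupied FLMOs (weight 2) and its
#' incident cut-bond shared orbitals (weight 1). Summed over fragments the
#' fragment densities reproduce the total density exactly.
#'
#' @param flmos A [localize_all()] result.
#' @param i Fragment index.
#' @return n_ao x n_ao symmetric matrix.
#' @export
fragment_density <- function(flmos, i) {
  fo <- flmos$fragment_orbitals[[i]]
  Cd <- flmos$coeff[, fo$doubly, drop = FALSE]
  Di <- 2 * tcrossprod(Cd)
  for (k in fo$shared) Di <- Di + tcrossprod(flmos$coeff[, k])
  Di
}

#' Mulliken locality metrics of orbitals
#'
#' For every orbital/fragment reference, the fraction of the orbital's
#' Mulliken population carried by AOs centered on that fragment. Shared
#' cut-bond orbitals are reported once per incident fragment (a symmetric
#' single bond gives about 0.5 on each side).
#'
#' @param flmos A [localize_all()] result (or any tagged orbital set with the
#'   same fields).
#' @param ints The matching [compute_integrals()] result.
#' @return Data frame with `orbital`, `fragment`, `fraction`.
#' @export
locality_metrics <- function(flmos, ints) {
  S <- ints$S
  fr <- ints$ao_map$fragment_ao
  rows <- list()
  for (k in seq_len(ncol(flmos$coeff))) {
    c_ <- flmos$coeff[, k]
    tot <- .mulliken_pop(c_, S, seq_len(ints$n_ao))
    tag <- flmos$fragment[k]
    frags <- if (is.na(tag)) {
      sh <- flmos$shared[flmos$shared$orbital == k, ]
      c(sh$fragment_a, sh$fragment_b)
    } else tag
    for (f in frags) {
      rows[[length(rows) + 1L]] <-
        data.frame(orbital = k, fragment = f,
                   fraction = .mulliken_pop(c_, S, fr[[f]]) / tot)
    }
  }
  do.call(rbind, rows)
}

# mean best-fragment Mulliken fraction of a plain orbital block (used to
# compare canonical MOs against FLMOs)
.best_fraction <- function(C, ints) {
  S <- ints$S
  fr <- ints$ao_map$fragment_ao
  vapply(seq_len(ncol(C)), function(k) {
    c_ <- C[, k]
    tot <- .mulliken_pop(c_, S, seq_len(ints$n_ao))
    max(vapply(fr, function(idx) .mulliken_pop(c_, S, idx) / tot, numeric(1)))
  }, numeric(1))
}
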