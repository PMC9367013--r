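#' Electrostatic and exchange interaction between two fragment densities
#'
#' The pair electrostatic energy collects the cross one-electron
#' (electron-nuclear), cross Coulomb and internuclear terms; the exchange term
#' is the cross exchange contraction, which is always non-positive. The
#' grouping is pinned by the exact identity
#' `E_HF = sum_i E^i + sum_{i<j} (E_ele^ij + E_ex^ij)`.
#'
#' @param Di,Dj Fragment density matrices on the full AO basis.
#' @param ints The [compute_integrals()] result.
#' @param i,j Fragment indices (for nuclear terms).
#' @return List with `e_ele` and `e_ex` (Hartree).
#' @export
pair_interaction <- function(Di, Dj, ints, i, j) {
  Vi <- ints$V_frag[[i]]; Vj <- ints$V_frag[[j]]
  e_ele <- sum(Vj * Di) + sum(Vi * Dj) + sum(coulomb_matrix(ints, Dj) * Di) +
    ints$nuclear_repulsion_pair[i, j]
  e_ex <- -0.5 * sum(exchange_matrix(ints, Dj) * Di)
  list(e_ele = e_ele, e_ex = e_ex)
}

# vacuum SCF of a fragment union; full_basis = TRUE reuses the supersystem
# integral set with ghost centers (counterpoise), FALSE rebuilds integrals on
# the union's own atoms/basis
.vacuum_scf <- function(fit, frags, full_basis) {
  ints <- fit$ints; scheme <- fit$scheme
  cb <- scheme$cut_bonds
  # cut bonds internal to the union recombine; bonds to outside stay open
  open_bonds <- sum((cb$fragment_a %in% frags) != (cb$fragment_b %in% frags))
  nelec <- sum(scheme$n_electrons[frags])
  mult <- open_bonds + 1L
  if (full_basis) {
    h <- ints$T
    for (i in frags) h <- h + ints$V_frag[[i]]
    hn <- sum(ints$nuclear_repulsion_frag[frags])
    if (length(frags) > 1) {
      pr <- utils::combn(frags, 2)
      hn <- hn + sum(ints$nuclear_repulsion_pair[t(pr)])
    }
    if (mult == 1L && nelec %% 2L == 0L) {
      scf_rhf(ints, n_electrons = nelec, h = h, h_nuc = hn)
    } else {
      scf_uhf(ints, n_electrons = nelec, multiplicity = mult, h = h, h_nuc = hn)
    }
  } else {
    atoms <- sort(unlist(scheme$fragment_atoms[frags]))
    sub <- molecular_system(fit$system$symbols[atoms],
                            fit$system$coords[atoms, , drop = FALSE],
                            charge = sum(scheme$fragment_charge[frags]),
                            multiplicity = mult, unit = "bohr")
    sints <- compute_integrals(sub, basis = fit$basis)
    if (mult == 1L && nelec %% 2L == 0L) {
      scf_rhf(sints)
    } else {
      scf_uhf(sints)
    }
  }
}

#' Electronic preparation energy of a fragment or fragment pair
#'
#' The energy cost of deforming a fragment's (or dimer's) electron density
#' from its isolated vacuum state to its in-complex state: embedded energy
#' minus a fresh vacuum SCF (restricted for closed shells, unrestricted for
#' open-shell cut-bond fragments). In counterpoise (`full_basis = TRUE`) mode
#' the vacuum SCF uses all AOs of the total system with ghost centers.
#'
#' @param fit A fitted [flmo()] object.
#' @param frags One fragment index, or two for a dimer.
#' @param full_basis Counterpoise mode flag.
#' @return List with `e_prep`, `e_embedded`, `e_vacuum`, `scf` (the vacuum
#'   run).
#' @export
electronic_preparation <- function(fit, frags, full_basis = FALSE) {
  frags <- as.integer(frags)
  stopifnot(length(frags) %in% 1:2)
  ints <- fit$ints
  if (length(frags) == 1L) {
    e_emb <- fit$fragment_energies[frags]
  } else {
    Di <- fragment_density(fit$orbitals, frags[1])
    Dj <- fragment_density(fit$orbitals, frags[2])
    pe <- pair_interaction(Di, Dj, ints, frags[1], frags[2])
    e_emb <- sum(fit$fragment_energies[frags]) + pe$e_ele + pe$e_ex
  }
  vac <- .vacuum_scf(fit, frags, full_basis)
  if (!vac$converged) warning("vacuum SCF for fragment(s) ",
                              paste(frags, collapse = ","), " not converged")
  list(e_prep = e_emb - vac$energy, e_embedded = e_emb,
       e_vacuum = vac$energy, scf = vac)
}

#' Decompose a fragment-pair interaction over orbital pairs
#'
#' Splits the electron-electron Coulomb part of the pair electrostatic energy
#' and the whole exchange term over pairs of FLMOs (one from each fragment).
#' Summing `e_coulomb` over all pairs recovers `Tr[J(D^j) D^i]` and summing
#' `e_exchange` recovers `E_ex^ij` exactly; one-electron and nuclear parts of
#' the electrostatics are not orbital-pairwise and are not included.
#'
#' @param fit A fitted [flmo()] object.
#' @param i,j Fragment indices.
#' @return Data frame with `orbital_i`, `orbital_j`, `occ_i`, `occ_j`,
#'   `e_coulomb`, `e_exchange` (Hartree), sorted by decreasing
#'   `|e_exchange|`.
#' @export
mo_pair_decompose <- function(fit, i, j) {
  ints <- fit$ints
  orb <- fit$orbitals
  oi <- orb$fragment_orbitals[[i]]
  oj <- orb$fragment_orbitals[[j]]
  idx_i <- c(oi$doubly, oi$shared)
  occ_i <- c(rep(2, length(oi$doubly)), rep(1, length(oi$shared)))
  idx_j <- c(oj$doubly, oj$shared)
  occ_j <- c(rep(2, length(oj$doubly)), rep(1, length(oj$shared)))
  rows <- vector("list", length(idx_i) * length(idx_j))
  n <- 0L
  for (a in seq_along(idx_i)) {
    ca <- orb$coeff[, idx_i[a]]
    Pa <- tcrossprod(ca)
    Ja <- coulomb_matrix(ints, Pa)
    Ka <- exchange_matrix(ints, Pa)
    for (b in seq_along(idx_j)) {
      cb <- orb$coeff[, idx_j[b]]
      w <- occ_i[a] * occ_j[b]
      n <- n + 1L
      rows[[n]] <- data.frame(
        orbital_i = idx_i[a], orbital_j = idx_j[b],
        occ_i = occ_i[a], occ_j = occ_j[b],
        e_coulomb = w * sum(cb * (Ja %*% cb)),
        e_exchange = -0.5 * w * sum(cb * (Ka %*% cb)))
    }
  }
  out <- do.call(rbind, rows)
  out[order(-abs(out$e_exchange)), ]
}

#' Fragment-pair interaction energy decomposition
#'
#' Computes the full decomposition on a fitted FLMO object: per-pair
#' electrostatic and exchange terms, per-fragment electronic preparation
#' (embedded minus vacuum energy), pair totals, dispersion (when a provider
#' is supplied) and the global total interaction energy, which satisfies
#' `E_int_tot = E_HF - sum_i E_vac,i` up to the SCF/localization tolerances.
#'
#' @param fit A fitted [flmo()] object.
#' @param counterpoise Logical: compute vacuum energies in the full AO basis
#'   with ghost centers. Default: `TRUE` for purely noncovalent partitions,
#'   `FALSE` when cut bonds are present (ghost-basis fragments with dangling
#'   bonds are ill-conditioned).
#' @param pair_prep `"monomer"` (default): pair totals use the two monomer
#'   preparation energies; `"dimer"`: pair totals use a dimer-in-vacuum SCF
#'   preparation term (one extra SCF per pair).
#' @param dispersion Optional dispersion provider (see
#'   [dispersion_partition()]); `NULL` disables dispersion and reports it as
#'   unavailable.
#' @param mo_pairs Logical: attach per-MO-pair decompositions for every pair.
#' @return An object of class `flmo_eda` with elements `pairs` (data frame),
#'   `fragments` (data frame), `global` (list with `e_hf`, `e_int_total`,
#'   `consistency_residual`, flags) and optionally `mo_pairs`.
#' @examples
#' fit <- flmo(fixture_system("he_pair", r = 10), list(1, 2))
#' eda(fit, counterpoise = FALSE)
#' @export
eda <- function(fit, counterpoise = NULL,
                pair_prep = c("monomer", "dimer"),
                dispersion = NULL, mo_pairs = FALSE) {
  stopifnot(inherits(fit, "flmo"))
  pair_prep <- match.arg(pair_prep)
  scheme <- fit$scheme
  nf <- scheme$n_fragments
  if (is.null(counterpoise)) counterpoise <- nrow(scheme$cut_bonds) == 0L
  ints <- fit$ints

  Dl <- lapply(seq_len(nf), function(i) fragment_density(fit$orbitals, i))

  prep <- lapply(seq_len(nf), function(i) {
    electronic_preparation(fit, i, full_basis = counterpoise)
  })
  frag_tbl <- data.frame(
    fragment = seq_len(nf),
    e_embedded = fit$fragment_energies,
    e_vacuum = vapply(prep, `[[`, numeric(1), "e_vacuum"),
    e_prep = vapply(prep, `[[`, numeric(1), "e_prep"))

  disp_tbl <- NULL
  if (!is.null(dispersion)) {
    disp_tbl <- dispersion_partition(fit$system, scheme, provider = dispersion)
  }

  pr <- list()
  if (nf > 1) {
    for (i in seq_len(nf - 1)) for (j in (i + 1):nf) {
      pe <- pair_interaction(Dl[[i]], Dl[[j]], ints, i, j)
      e_prep_pair <- if (pair_prep == "monomer") {
        frag_tbl$e_prep[i] + frag_tbl$e_prep[j]
      } else {
        electronic_preparation(fit, c(i, j), full_basis = counterpoise)$e_prep
      }
      e_disp <- if (!is.null(disp_tbl)) disp_tbl$pair_energy[i, j] else NA_real_
      e_tot <- pe$e_ele + pe$e_ex + e_prep_pair +
        if (!is.null(disp_tbl)) e_disp else 0
      pr[[length(pr) + 1L]] <- data.frame(
        fragment_i = i, fragment_j = j,
        e_ele = pe$e_ele, e_ex = pe$e_ex, e_prep = e_prep_pair,
        e_disp = e_disp, e_total = e_tot)
    }
  }
  pairs <- if (length(pr)) do.call(rbind, pr) else
    data.frame(fragment_i = integer(0), fragment_j = integer(0),
               e_ele = numeric(0), e_ex = numeric(0), e_prep = numeric(0),
               e_disp = numeric(0), e_total = numeric(0))

  e_pairs <- sum(pairs$e_ele + pairs$e_ex)
  e_disp_tot <- if (!is.null(disp_tbl)) sum(pairs$e_disp) else 0
  e_int_total <- e_pairs + sum(frag_tbl$e_prep) + e_disp_tot
  e_hf <- fit$scf$energy
  resid <- abs(e_hf - (sum(frag_tbl$e_embedded) + e_pairs))

  mp <- NULL
  if (mo_pairs && nf > 1) {
    mp <- list()
    for (r in seq_len(nrow(pairs))) {
      i <- pairs$fragment_i[r]; j <- pairs$fragment_j[r]
      mp[[paste(i, j, sep = "-")]] <- mo_pair_decompose(fit, i, j)
    }
  }

  structure(list(
    pairs = pairs, fragments = frag_tbl,
    global = list(e_hf = e_hf, e_int_total = e_int_total,
                  e_int_supermolecular = e_hf - sum(frag_tbl$e_vacuum),
                  consistency_residual = resid,
                  density_residual = fit$density_residual,
                  counterpoise = counterpoise, pair_prep = pair_prep,
                  dispersion_available = !is.null(disp_tbl)),
    dispersion = disp_tbl, mo_pairs = mp, fit_call = fit$call),
    class = "flmo_eda")
}

#' Total interaction energy from an EDA report
#'
#' @param report A [eda()] result.
#' @param unit `"hartree"` or `"kcal"`.
#' @return Scalar total interaction energy.
#' @export
total_interaction <- function(report, unit = c("hartree", "kcal")) {
  unit <- match.arg(unit)
  v <- report$global$e_int_total
  if (unit == "kcal") v * HARTREE_TO_KCAL else v
}
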