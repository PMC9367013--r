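#' Define a fragment partition of a molecular system
#'
#' Partitions the atoms into `N_f` disjoint fragments, assigns per-fragment
#' charges and records cut bonds (covalent bonds severed by the partition).
#' Each cut bond contributes one singly occupied orbital to each of the two
#' fragments sharing the bond; a fragment's number of singly occupied orbitals
#' therefore equals the number of cut bonds touching it, and its doubly
#' occupied count follows from its electron count.
#'
#' @param system A [molecular_system()].
#' @param fragments List of integer vectors of atom indices (1-based); must be
#'   disjoint and cover all atoms.
#' @param charges Integer vector of per-fragment charges summing to the total
#'   charge (default all zero).
#' @param cut_bonds Optional list of length-2 integer vectors `c(atom_a,
#'   atom_b)`, each joining atoms in two different fragments.
#' @return An object of class `fragment_scheme` with fields `n_fragments`,
#'   `fragment_atoms`, `fragment_charge`, `cut_bonds` (data frame with
#'   `atom_a`, `atom_b`, `fragment_a`, `fragment_b`), `n_electrons`,
#'   `n_doubly`, `n_singly`.
#' @examples
#' sys <- fixture_system("he_pair", r = 5)
#' fragment_scheme(sys, list(1, 2))
#' @export
fragment_scheme <- function(system, fragments, charges = NULL,
                            cut_bonds = list()) {
  stopifnot(inherits(system, "molecular_system"))
  n_atoms <- length(system$Z)
  fragments <- lapply(fragments, function(f) sort(as.integer(f)))
  all_idx <- sort(unlist(fragments))
  if (anyDuplicated(all_idx)) stop("fragment atom sets overlap")
  if (!identical(all_idx, seq_len(n_atoms))) {
    stop("fragment atom sets must form an exact partition of the atoms")
  }
  nf <- length(fragments)
  if (is.null(charges)) charges <- integer(nf)
  charges <- as.integer(charges)
  if (length(charges) != nf) stop("one charge per fragment required")
  if (sum(charges) != system$charge) {
    stop("fragment charges sum to ", sum(charges),
         " but the system charge is ", system$charge)
  }
  atom_frag <- integer(n_atoms)
  for (i in seq_len(nf)) atom_frag[fragments[[i]]] <- i

  cb <- data.frame(atom_a = integer(0), atom_b = integer(0),
                   fragment_a = integer(0), fragment_b = integer(0))
  for (b in cut_bonds) {
    b <- as.integer(b)
    if (length(b) != 2L) stop("each cut bond is a pair of atom indices")
    fa <- atom_frag[b[1]]; fb <- atom_frag[b[2]]
    if (fa == fb) stop("cut bond ", b[1], "-", b[2],
                       " joins atoms in the same fragment")
    cb <- rbind(cb, data.frame(atom_a = b[1], atom_b = b[2],
                               fragment_a = fa, fragment_b = fb))
  }

  n_singly <- vapply(seq_len(nf), function(i) {
    sum(cb$fragment_a == i) + sum(cb$fragment_b == i)
  }, integer(1))
  n_elec <- vapply(seq_len(nf), function(i) {
    as.integer(sum(system$Z[fragments[[i]]]) - charges[i])
  }, integer(1))
  if (any((n_elec - n_singly) %% 2L != 0L) || any(n_elec - n_singly < 0L)) {
    bad <- which((n_elec - n_singly) %% 2L != 0L | n_elec - n_singly < 0L)[1]
    stop("fragment ", bad, ": electron count ", n_elec[bad],
         " minus singly occupied count ", n_singly[bad],
         " must be a non-negative even number")
  }
  n_doubly <- (n_elec - n_singly) %/% 2L
  stopifnot(sum(2L * n_doubly + n_singly) == system$n_electrons)

  structure(list(n_fragments = nf, fragment_atoms = fragments,
                 fragment_charge = charges, cut_bonds = cb,
                 atom_fragment = atom_frag, n_electrons = n_elec,
                 n_doubly = n_doubly, n_singly = n_singly),
            class = "fragment_scheme")
}

# trivial single-fragment scheme covering the whole system; skips the
# closed-shell bookkeeping checks so open-shell molecules (vacuum radical
# fragments) can be handled as plain systems
.whole_scheme <- function(system) {
  n_open <- system$multiplicity - 1L
  structure(list(n_fragments = 1L,
                 fragment_atoms = list(seq_along(system$Z)),
                 fragment_charge = system$charge,
                 cut_bonds = data.frame(atom_a = integer(0),
                                        atom_b = integer(0),
                                        fragment_a = integer(0),
                                        fragment_b = integer(0)),
                 atom_fragment = rep(1L, length(system$Z)),
                 n_electrons = system$n_electrons,
                 n_doubly = (system$n_electrons - n_open) %/% 2L,
                 n_singly = n_open),
            class = "fragment_scheme")
}

#' @export
print.fragment_scheme <- function(x, ...) {
  cat("Fragment scheme:", x$n_fragments, "fragments\n")
  for (i in seq_len(x$n_fragments)) {
    cat(sprintf("  %d: %d atoms, charge %+d, %d doubly / %d singly occupied\n",
                i, length(x$fragment_atoms[[i]]), x$fragment_charge[i],
                x$n_doubly[i], x$n_singly[i]))
  }
  if (nrow(x$cut_bonds)) {
    cat("  cut bonds:",
        paste(sprintf("%d-%d", x$cut_bonds$atom_a, x$cut_bonds$atom_b),
              collapse = ", "), "\n")
  }
  invisible(x)
}
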