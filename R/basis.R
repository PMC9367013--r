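# double factorial (2l-1)!! for small l
.dfact2lm1 <- c(1, 1, 3, 15)

# primitive normalisation constant for a Cartesian Gaussian of the (l,0,0)
# type; p shells share it across components (and that is all we need: the
# bundled bases are s/p)
.prim_norm <- function(a, l) {
  (2 * a / pi)^0.75 * (2 * sqrt(a))^l / sqrt(.dfact2lm1[l + 1])
}

#' Build the AO basis for a system
#'
#' Expands a named basis set over the atoms of a system into a list of
#' contracted Cartesian Gaussian shells (with full normalisation folded into
#' the contraction coefficients) plus the atom -> AO index map.
#'
#' @param system A [molecular_system()].
#' @param basis Basis-set name, one of [available_bases()].
#' @return An object of class `ao_basis`: list with `shells` (each `l`,
#'   `center` in Bohr, `exps`, `coefs`, `atom`), `n_ao`, `ao_atom` (atom index
#'   per AO), `ao_label`.
#' @export
build_basis <- function(system, basis = "sto-3g") {
  basis <- tolower(basis)
  lib <- .BASIS_LIBRARY[[basis]]
  if (is.null(lib)) {
    stop("unknown basis '", basis, "'; available: ",
         paste(available_bases(), collapse = ", "))
  }
  missing_el <- setdiff(unique(system$symbols), names(lib))
  if (length(missing_el)) {
    stop("basis '", basis, "' not available for element(s): ",
         paste(missing_el, collapse = ", "))
  }
  shells <- list()
  ao_atom <- integer(0)
  ao_label <- character(0)
  comp <- list(`0` = "s", `1` = c("px", "py", "pz"),
               `2` = c("dxx", "dxy", "dxz", "dyy", "dyz", "dzz"))
  for (ia in seq_along(system$Z)) {
    for (tmpl in lib[[system$symbols[ia]]]) {
      l <- tmpl$l
      coefs <- tmpl$coefs * .prim_norm(tmpl$exps, l)
      # normalise the contracted function to unit self-overlap
      pp <- outer(tmpl$exps, tmpl$exps, `+`)
      s_self <- sum(outer(coefs, coefs) * (pi / pp)^1.5 *
                      .dfact2lm1[l + 1] / (2 * pp)^l)
      coefs <- coefs / sqrt(s_self)
      shells[[length(shells) + 1L]] <-
        list(l = l, center = system$coords[ia, ], exps = tmpl$exps,
             coefs = coefs, atom = ia)
      nc <- (l + 1) * (l + 2) / 2
      ao_atom <- c(ao_atom, rep(ia, nc))
      ao_label <- c(ao_label,
                    paste0(system$symbols[ia], ia, " ", comp[[as.character(l)]]))
    }
  }
  structure(list(shells = shells, n_ao = length(ao_atom), ao_atom = ao_atom,
                 ao_label = ao_label, name = basis),
            class = "ao_basis")
}

#' Map AOs to fragments
#'
#' Assigns every AO to exactly one fragment: the fragment of the atom on which
#' it is centered.
#'
#' @param basis An [build_basis()] result.
#' @param scheme A [fragment_scheme()].
#' @return An object of class `ao_map`: list with `n_ao`, `fragment_ao`
#'   (per-fragment AO index vectors) and `ao_fragment` (fragment per AO).
#' @export
build_ao_map <- function(basis, scheme) {
  stopifnot(inherits(basis, "ao_basis"), inherits(scheme, "fragment_scheme"))
  ao_fragment <- scheme$atom_fragment[basis$ao_atom]
  fragment_ao <- lapply(seq_len(scheme$n_fragments),
                        function(i) which(ao_fragment == i))
  stopifnot(identical(sort(unlist(fragment_ao)), seq_len(basis$n_ao)))
  structure(list(n_ao = basis$n_ao, fragment_ao = fragment_ao,
                 ao_fragment = ao_fragment),
            class = "ao_map")
}
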