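#' @useDynLib flmoeda, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats setNames
#' @importFrom utils write.csv modifyList tail head
NULL

# unit conversions used throughout: coordinates are stored in Bohr,
# energies in Hartree; human-facing reports add kcal/mol
BOHR_PER_ANGSTROM <- 1.8897259886
HARTREE_TO_KCAL <- 627.509474

#' Physical constants used by the package
#'
#' @return Named list with `bohr_per_angstrom` and `hartree_to_kcal`.
#' @export
flmo_constants <- function() {
  list(bohr_per_angstrom = BOHR_PER_ANGSTROM,
       hartree_to_kcal = HARTREE_TO_KCAL)
}

# element symbol -> nuclear charge, first three rows (ample for the fixtures)
.ELEMENTS <- c(
  H = 1, He = 2, Li = 3, Be = 4, B = 5, C = 6, N = 7, O = 8, F = 9, Ne = 10,
  Na = 11, Mg = 12, Al = 13, Si = 14, P = 15, S = 16, Cl = 17, Ar = 18
)

element_Z <- function(symbol) {
  sym <- paste0(toupper(substr(symbol, 1, 1)), tolower(substring(symbol, 2)))
  z <- .ELEMENTS[sym]
  if (any(is.na(z))) {
    stop("unknown element symbol(s): ", paste(symbol[is.na(z)], collapse = ", "))
  }
  unname(z)
}

element_symbol <- function(Z) {
  names(.ELEMENTS)[match(Z, .ELEMENTS)]
}
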