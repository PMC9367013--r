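#' Construct a molecular system
#'
#' A `molecular_system` holds the nuclei (element symbols, nuclear charges and
#' Cartesian positions) together with the total charge and spin multiplicity.
#' Positions are stored internally in Bohr.
#'
#' @param symbols Character vector of element symbols.
#' @param coords Numeric matrix (n_atoms x 3) of positions.
#' @param charge Integer total charge (default 0).
#' @param multiplicity Integer spin multiplicity 2S+1 (default 1).
#' @param unit Unit of `coords`: `"angstrom"` (default) or `"bohr"`.
#' @return An object of class `molecular_system` with elements `symbols`, `Z`,
#'   `coords` (Bohr), `charge`, `multiplicity`, `n_electrons`.
#' @examples
#' molecular_system("He", matrix(0, 1, 3))
#' @export
molecular_system <- function(symbols, coords, charge = 0L, multiplicity = 1L,
                             unit = c("angstrom", "bohr")) {
  unit <- match.arg(unit)
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L || nrow(coords) != length(symbols)) {
    stop("coords must be an n_atoms x 3 matrix matching 'symbols'")
  }
  if (!all(is.finite(coords))) stop("non-finite coordinates")
  Z <- element_Z(symbols)
  if (unit == "angstrom") coords <- coords * BOHR_PER_ANGSTROM
  nelec <- sum(Z) - charge
  if (nelec < 0 || nelec != round(nelec)) {
    stop("electron count (sum Z - charge) must be a non-negative integer")
  }
  structure(list(symbols = element_symbol(Z), Z = Z, coords = unname(coords),
                 charge = as.integer(charge),
                 multiplicity = as.integer(multiplicity),
                 n_electrons = as.integer(nelec)),
            class = "molecular_system")
}

#' @export
print.molecular_system <- function(x, ...) {
  cat("Molecular system:", length(x$Z), "atoms,",
      x$n_electrons, "electrons, charge", x$charge,
      ", multiplicity", x$multiplicity, "\n")
  invisible(x)
}

#' Read a molecule from an XYZ file
#'
#' Standard XYZ: first line atom count, second line comment, then one
#' `symbol x y z` line per atom with coordinates in Angstrom.
#'
#' @param path File path.
#' @param charge,multiplicity Passed to [molecular_system()].
#' @return A [molecular_system()].
#' @export
read_xyz <- function(path, charge = 0L, multiplicity = 1L) {
  lines <- readLines(path)
  if (length(lines) < 1L) stop("empty XYZ file: ", path)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n)) stop("malformed XYZ header (atom count): ", path)
  if (length(lines) < n + 2L) stop("XYZ file shorter than declared atom count")
  body <- lines[3:(n + 2L)]
  toks <- strsplit(trimws(body), "\\s+")
  bad <- vapply(toks, length, 1L) < 4L
  if (any(bad)) stop("malformed XYZ atom line(s): ", which(bad)[1] + 2L)
  symbols <- vapply(toks, `[[`, "", 1L)
  coords <- t(vapply(toks, function(t) as.numeric(t[2:4]), numeric(3)))
  if (!all(is.finite(coords))) stop("non-numeric coordinates in XYZ file")
  molecular_system(symbols, coords, charge, multiplicity, unit = "angstrom")
}

#' Write a molecular system to an XYZ file
#'
#' @param system A [molecular_system()].
#' @param path Output path.
#' @param comment Comment line.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(system, path, comment = "written by flmoeda") {
  ang <- system$coords / BOHR_PER_ANGSTROM
  lines <- c(length(system$Z), comment,
             sprintf("%-2s %18.10f %18.10f %18.10f",
                     system$symbols, ang[, 1], ang[, 2], ang[, 3]))
  writeLines(lines, path)
  invisible(path)
}

#' Read elements and coordinates from a PDB file
#'
#' Convenience reader for ATOM/HETATM records only: extracts element symbols
#' and coordinates. Residue identifiers are returned to support residue-based
#' fragment suggestions ([residue_fragments()]); the canonical fragment input
#' remains explicit atom-index sets.
#'
#' @param path File path.
#' @param charge,multiplicity Passed to [molecular_system()].
#' @return A [molecular_system()] with an extra `residues` attribute
#'   (character vector `chain:resSeq` per atom).
#' @export
read_pdb <- function(path, charge = 0L, multiplicity = 1L) {
  lines <- readLines(path)
  rec <- lines[startsWith(lines, "ATOM") | startsWith(lines, "HETATM")]
  if (length(rec) == 0L) stop("no ATOM/HETATM records in ", path)
  x <- as.numeric(substr(rec, 31, 38))
  y <- as.numeric(substr(rec, 39, 46))
  z <- as.numeric(substr(rec, 47, 54))
  elem <- trimws(substr(rec, 77, 78))
  # fall back to the atom-name column when the element field is blank
  blank <- elem == ""
  if (any(blank)) {
    nm <- trimws(substr(rec[blank], 13, 16))
    elem[blank] <- gsub("[^A-Za-z].*$", "", nm)
    elem[blank] <- substr(elem[blank], 1, ifelse(
      toupper(elem[blank]) %in% c("HE", "LI", "BE", "NE", "NA", "MG", "AL",
                                  "SI", "CL", "AR"), 2, 1))
  }
  sys <- molecular_system(elem, cbind(x, y, z), charge, multiplicity,
                          unit = "angstrom")
  chain <- substr(rec, 22, 22)
  resseq <- trimws(substr(rec, 23, 26))
  attr(sys, "residues") <- paste(chain, resseq, sep = ":")
  sys
}

#' Suggest a fragment partition from PDB residues
#'
#' Groups atoms by their `chain:resSeq` identifier, a helper for building
#' explicit atom-index fragment sets from protein structures.
#'
#' @param system A system read with [read_pdb()].
#' @return Named list of atom-index vectors, one per residue.
#' @export
residue_fragments <- function(system) {
  res <- attr(system, "residues")
  if (is.null(res)) stop("system carries no residue information (use read_pdb)")
  split(seq_along(res), factor(res, levels = unique(res)))
}
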