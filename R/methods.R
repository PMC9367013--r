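#' @export
print.flmo <- function(x, ...) {
  cat("Fragment localized molecular orbitals\n")
  cat(sprintf("  %d atoms, %d fragments, basis %s (%d AOs)\n",
              length(x$system$Z), x$scheme$n_fragments, x$basis,
              x$ints$n_ao))
  cat(sprintf("  E_HF = %.10f Hartree (%s)\n", x$scf$energy,
              if (x$scf$converged) "converged" else "NOT converged"))
  cat(sprintf("  density partition residual %.2e, energy residual %.2e Ha\n",
              x$density_residual, x$energy_residual))
  invisible(x)
}

#' Summary of a fitted FLMO model
#'
#' Per-fragment embedded energies, localization traces and Mulliken locality
#' (mean own-fragment fraction of the FLMOs against the best-fragment
#' fraction of the canonical occupied MOs).
#'
#' @param object A fitted [flmo()] object.
#' @param ... Unused.
#' @return An object of class `summary.flmo`, printed with its own method.
#' @export
summary.flmo <- function(object, ...) {
  loc <- locality_metrics(object$orbitals, object$ints)
  nocc <- object$system$n_electrons %/% 2L
  canon <- .best_fraction(object$scf$C[, seq_len(nocc), drop = FALSE],
                          object$ints)
  own <- loc$fraction[!is.na(object$orbitals$fragment[loc$orbital])]
  iters <- vapply(object$orbitals$traces, length, 1L)
  out <- list(
    fit = object,
    fragment_table = data.frame(
      fragment = seq_len(object$scheme$n_fragments),
      e_embedded = object$fragment_energies,
      iterations = iters,
      converged = object$orbitals$converged),
    locality = loc,
    mean_flmo_fraction = mean(own),
    mean_canonical_fraction = mean(canon))
  class(out) <- "summary.flmo"
  out
}

#' @export
print.summary.flmo <- function(x, ...) {
  print(x$fit)
  cat("\nFragment energies (Hartree):\n")
  print(x$fragment_table, row.names = FALSE)
  cat(sprintf("\nMean own-fragment Mulliken fraction: FLMO %.4f vs canonical %.4f\n",
              x$mean_flmo_fraction, x$mean_canonical_fraction))
  invisible(x)
}

#' Extract FLMO coefficients
#'
#' @param object A fitted [flmo()] object.
#' @param ... Unused.
#' @return n_ao x n_occ coefficient matrix with fragment tags in
#'   `attr(,"fragment")`.
#' @export
coef.flmo <- function(object, ...) {
  out <- object$orbitals$coeff
  attr(out, "fragment") <- object$orbitals$fragment
  out
}

#' Plot locality of the fitted FLMOs
#'
#' Bar plot of per-orbital own-fragment Mulliken fractions.
#'
#' @param x A fitted [flmo()] object.
#' @param ... Passed to [graphics::barplot()].
#' @return The locality data frame, invisibly.
#' @export
plot.flmo <- function(x, ...) {
  loc <- locality_metrics(x$orbitals, x$ints)
  graphics::barplot(loc$fraction,
                    names.arg = paste0(loc$orbital, "/", loc$fragment),
                    ylab = "own-fragment Mulliken fraction",
                    xlab = "orbital/fragment", ylim = c(0, 1.05), ...)
  invisible(loc)
}

#' @export
print.flmo_eda <- function(x, ...) {
  k <- HARTREE_TO_KCAL
  cat("FLMO interaction energy decomposition",
      sprintf("(counterpoise %s, %s preparation)\n",
              if (x$global$counterpoise) "on" else "off", x$global$pair_prep))
  if (nrow(x$pairs)) {
    tbl <- eda_table(x)
    print(format(tbl, digits = 4), row.names = FALSE)
  }
  cat(sprintf("total interaction energy: %.6f Hartree (%.3f kcal/mol)\n",
              x$global$e_int_total, x$global$e_int_total * k))
  if (!x$global$dispersion_available) {
    cat("dispersion: unavailable (no provider)\n")
  }
  cat(sprintf("conservation residual: %.2e Hartree\n",
              x$global$consistency_residual))
  invisible(x)
}

#' @export
summary.flmo_eda <- function(object, ...) {
  print(object)
  cat("\nPer-fragment energies (Hartree):\n")
  print(format(object$fragments, digits = 10), row.names = FALSE)
  invisible(object)
}

#' @export
as.data.frame.flmo_eda <- function(x, ...) x$pairs

#' Bar chart of EDA components per fragment pair
#'
#' @param x A [eda()] result.
#' @param ... Passed to [graphics::barplot()].
#' @return Invisibly, the plotted matrix (kcal/mol).
#' @export
plot.flmo_eda <- function(x, ...) {
  if (!nrow(x$pairs)) {
    warning("no fragment pairs to plot")
    return(invisible(NULL))
  }
  tbl <- eda_table(x)
  m <- t(as.matrix(tbl[, c("e_ele_kcal", "e_ex_kcal", "e_prep_kcal",
                           "e_total_kcal")]))
  colnames(m) <- paste(tbl$fragment_i, tbl$fragment_j, sep = "-")
  graphics::barplot(m, beside = TRUE,
                    legend.text = c("electrostatic", "exchange",
                                    "preparation", "total"),
                    ylab = "kcal/mol", xlab = "fragment pair", ...)
  invisible(m)
}
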