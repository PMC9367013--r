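# evaluate all AOs on a set of points (npts x 3, Bohr) -> npts x n_ao
.evaluate_aos <- function(basis, pts) {
  n <- nrow(pts)
  out <- matrix(0, n, basis$n_ao)
  col <- 1L
  for (sh in basis$shells) {
    dx <- pts[, 1] - sh$center[1]
    dy <- pts[, 2] - sh$center[2]
    dz <- pts[, 3] - sh$center[3]
    r2 <- dx * dx + dy * dy + dz * dz
    radial <- rep(0, n)
    for (p in seq_along(sh$exps)) {
      radial <- radial + sh$coefs[p] * exp(-sh$exps[p] * r2)
    }
    if (sh$l == 0) {
      out[, col] <- radial
      col <- col + 1L
    } else if (sh$l == 1) {
      out[, col] <- dx * radial
      out[, col + 1L] <- dy * radial
      out[, col + 2L] <- dz * radial
      col <- col + 3L
    } else {
      stop("cube export supports s and p shells")
    }
  }
  out
}

#' Export a density or orbital to a Gaussian cube file
#'
#' Writes a fragment density, the total density, or a single FLMO on a
#' regular grid in Gaussian cube format for visualization.
#'
#' @param fit A fitted [flmo()] object.
#' @param path Output file path.
#' @param what `"fragment_density"`, `"total_density"` or `"orbital"`.
#' @param fragment Fragment index (for `"fragment_density"`).
#' @param orbital FLMO column index (for `"orbital"`).
#' @param npts Grid points per axis.
#' @param margin Box margin around the nuclei, Bohr.
#' @return `path`, invisibly.
#' @export
write_cube <- function(fit, path, what = c("fragment_density",
                                           "total_density", "orbital"),
                       fragment = 1L, orbital = 1L, npts = 40L, margin = 4) {
  what <- match.arg(what)
  sys <- fit$system
  lo <- apply(sys$coords, 2, min) - margin
  hi <- apply(sys$coords, 2, max) + margin
  step <- (hi - lo) / (npts - 1)
  ax <- lapply(1:3, function(d) lo[d] + step[d] * (seq_len(npts) - 1))

  header <- c(
    sprintf("flmoeda cube: %s", what),
    sprintf("fragment=%d orbital=%d", fragment, orbital),
    sprintf("%5d %11.6f %11.6f %11.6f", length(sys$Z), lo[1], lo[2], lo[3]),
    sprintf("%5d %11.6f %11.6f %11.6f", npts, step[1], 0, 0),
    sprintf("%5d %11.6f %11.6f %11.6f", npts, 0, step[2], 0),
    sprintf("%5d %11.6f %11.6f %11.6f", npts, 0, 0, step[3]),
    sprintf("%5d %11.6f %11.6f %11.6f %11.6f", sys$Z, sys$Z,
            sys$coords[, 1], sys$coords[, 2], sys$coords[, 3]))

  M <- switch(what,
    fragment_density = fragment_density(fit$orbitals, fragment),
    total_density = fit$scf$D,
    orbital = NULL)
  cvec <- if (what == "orbital") fit$orbitals$coeff[, orbital] else NULL

  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  # x slowest, z fastest; evaluate one x-slab at a time to bound memory
  yz <- expand.grid(z = ax[[3]], y = ax[[2]])[, c("y", "z")]
  for (ix in seq_len(npts)) {
    pts <- cbind(ax[[1]][ix], yz$y, yz$z)
    ao <- .evaluate_aos(fit$ints$basis, pts)
    vals <- if (what == "orbital") as.vector(ao %*% cvec) else
      rowSums((ao %*% M) * ao)
    # grid order within the slab: y outer, z inner (already so in yz)
    for (iy in seq_len(npts)) {
      v <- vals[(iy - 1) * npts + seq_len(npts)]
      idx <- seq(1, npts, by = 6)
      for (s in idx) {
        writeLines(paste(sprintf("%13.5E", v[s:min(s + 5, npts)]),
                         collapse = " "), con)
      }
    }
  }
  invisible(path)
}
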