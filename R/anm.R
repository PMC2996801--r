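#' Anisotropic network model Hessian
#'
#' The 3n x 3n second-derivative matrix of the pairwise harmonic potential
#' `V = (gamma/2) * sum over in-cutoff pairs (|r_ij| - |r_ij^0|)^2` evaluated
#' at the equilibrium (input) coordinates. The off-diagonal 3x3 block for a
#' pair within the cutoff has entries
#' `-gamma * (a_j - a_i)(b_j - b_i) / R_ij^2` for coordinates a, b in
#' (x, y, z); the diagonal block is minus the sum of the node's off-diagonal
#' blocks, which makes the matrix translation-invariant by construction.
#'
#' @param structure a [cg_structure()].
#' @param cutoff ANM cutoff distance in Angstrom (default 13; the ANM uses a
#'   larger cutoff than the GNM because the directional springs are sparser
#'   per mode).
#' @param gamma spring constant; a pure scale on the spectrum, fixed to 1 by
#'   convention.
#' @return Symmetric `3n x 3n` numeric matrix.
#' @export
anm_hessian <- function(structure, cutoff = 13, gamma = 1) {
  stopifnot(inherits(structure, "cg_structure"), cutoff > 0)
  xyz <- structure$xyz
  n <- nrow(xyz)
  d <- as.matrix(stats::dist(xyz))
  H <- matrix(0, 3 * n, 3 * n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (d[i, j] > cutoff) next
      if (d[i, j] < 1e-6) {
        stop(sprintf("coincident nodes %d and %d (distance %.2g A)",
                     i, j, d[i, j]))
      }
      dr <- xyz[j, ] - xyz[i, ]
      blk <- -gamma * tcrossprod(dr) / d[i, j]^2
      ri <- (3 * i - 2):(3 * i)
      rj <- (3 * j - 2):(3 * j)
      H[ri, rj] <- blk
      H[rj, ri] <- blk
      H[ri, ri] <- H[ri, ri] - blk
      H[rj, rj] <- H[rj, rj] - blk
    }
  }
  H
}

#' Fit an anisotropic network model
#'
#' Builds the ANM Hessian and decomposes it. A generic (non-collinear) rigid
#' structure has exactly 6 zero modes (3 translations + 3 rotations); a
#' collinear one has 5. Zero modes are identified by the same relative
#' eigenvalue tolerance as the GNM.
#'
#' @inheritParams anm_hessian
#' @param zero_tolerance relative eigenvalue tolerance for zero modes.
#' @return An object of class `anm`: list with `structure`, `hessian`,
#'   mode `spectrum` (kind `"anm"`), `cutoff` and `gamma`.
#' @seealso [mode_field()], [anm_mobility()]
#' @examples
#' a <- anm(toy_zinc_finger(), cutoff = 13)
#' a$spectrum$n_zero  # 6 rigid-body modes
#' @export
anm <- function(structure, cutoff = 13, gamma = 1, zero_tolerance = 1e-8) {
  H <- anm_hessian(structure, cutoff, gamma)
  spectrum <- decompose_modes(H, zero_tolerance, kind = "anm")
  structure(list(structure = structure, hessian = H, spectrum = spectrum,
                 cutoff = cutoff, gamma = gamma),
            class = "anm")
}

#' @export
print.anm <- function(x, ...) {
  n <- nrow(x$structure$xyz)
  cat(sprintf("Anisotropic network model: %d nodes (%d dof), cutoff %.1f A\n",
              n, 3 * n, x$cutoff))
  cat(sprintf("  zero (rigid-body) modes: %d; slowest internal eigenvalue %.4g\n",
              x$spectrum$n_zero,
              x$spectrum$values[x$spectrum$n_zero + 1]))
  invisible(x)
}

#' @export
summary.anm <- function(object, ...) {
  f1 <- mode_field(object, 1)
  out <- list(n_nodes = nrow(object$structure$xyz),
              cutoff = object$cutoff,
              n_zero = object$spectrum$n_zero,
              slowest_eigenvalue = f1$eigenvalue,
              top_nodes = order(f1$magnitudes, decreasing = TRUE)[1:5])
  class(out) <- "summary.anm"
  out
}

#' @export
print.summary.anm <- function(x, ...) {
  cat(sprintf("ANM: %d nodes, cutoff %.1f A, %d rigid-body modes\n",
              x$n_nodes, x$cutoff, x$n_zero))
  cat(sprintf("  slowest internal mode: eigenvalue %.4g; largest amplitudes at nodes %s\n",
              x$slowest_eigenvalue, paste(x$top_nodes, collapse = ", ")))
  invisible(x)
}

#' Per-node displacement field of an ANM mode
#'
#' Reshapes the eigenvector of the requested internal (nonzero) mode into one
#' 3-vector per node, with Euclidean magnitudes. The full 3n vector has unit
#' norm, and its net displacement is zero (orthogonality to the translation
#' modes). These vectors are what cone/porcupine renderings display.
#'
#' @param x an `anm` object (or an ANM `mode_spectrum`).
#' @param mode_rank 1 = slowest internal mode, counting up from the smallest
#'   nonzero eigenvalue.
#' @return An object of class `anm_mode_field`: list with `vectors` (n x 3),
#'   `magnitudes` (length n), `eigenvalue`, `mode_rank`.
#' @export
mode_field <- function(x, mode_rank = 1) {
  sp <- if (inherits(x, "anm")) x$spectrum else x
  stopifnot(inherits(sp, "mode_spectrum"), sp$kind == "anm")
  idx <- nonzero_mode_index(sp, as.integer(mode_rank))
  v <- sp$vectors[, idx]
  vec <- matrix(v, ncol = 3, byrow = TRUE)
  structure(list(vectors = vec, magnitudes = sqrt(rowSums(vec^2)),
                 eigenvalue = sp$values[idx], mode_rank = as.integer(mode_rank)),
            class = "anm_mode_field")
}

#' @export
print.anm_mode_field <- function(x, ...) {
  cat(sprintf("ANM mode field: rank %d, eigenvalue %.4g, %d nodes\n",
              x$mode_rank, x$eigenvalue, nrow(x$vectors)))
  cat(sprintf("  largest magnitude %.3g at node %d\n",
              max(x$magnitudes), which.max(x$magnitudes)))
  invisible(x)
}

#' Per-node ANM mobility
#'
#' Shape of the mean-square displacement implied by the ANM: for each node,
#' the sum over internal modes of `|v_i|^2 / lambda`. Useful for consistency
#' checks against GNM mean-square fluctuations.
#'
#' @param x an `anm` object.
#' @return Numeric vector, one value per node (arbitrary scale).
#' @export
anm_mobility <- function(x) {
  stopifnot(inherits(x, "anm"))
  sp <- x$spectrum
  nz <- nonzero_mode_index(sp)
  n <- nrow(x$structure$xyz)
  mob <- numeric(n)
  for (k in nz) {
    vec <- matrix(sp$vectors[, k], ncol = 3, byrow = TRUE)
    mob <- mob + rowSums(vec^2) / sp$values[k]
  }
  mob
}

#' Plot the magnitudes of an ANM mode
#'
#' @param x an `anm` object.
#' @param mode_rank internal mode to display.
#' @param ... passed to `plot`.
#' @return `x`, invisibly.
#' @export
plot.anm <- function(x, mode_rank = 1, ...) {
  f <- mode_field(x, mode_rank)
  plot(seq_along(f$magnitudes), f$magnitudes, type = "h", xlab = "node",
       ylab = sprintf("|v| (mode %d)", mode_rank), ...)
  invisible(x)
}
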