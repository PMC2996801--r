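#' Eigendecomposition of a network matrix with zero-mode bookkeeping
#'
#' Decomposes a symmetric Kirchhoff (GNM) or Hessian (ANM) matrix into
#' ascending eigenvalues and orthonormal eigenvectors, flags (near-)zero
#' modes, and supports a spectral Moore-Penrose pseudo-inverse restricted to
#' the nonzero modes.
#'
#' @param matrix symmetric numeric matrix.
#' @param zero_tolerance relative tolerance: eigenvalues at or below
#'   `zero_tolerance * max(abs(eigenvalues))` are treated as exact zeros
#'   (default 1e-8). A connected GNM network has exactly one zero mode; in
#'   general their count equals the number of connected components (GNM) or
#'   the number of rigid-body degrees of freedom (ANM).
#' @param kind `"gnm"` or `"anm"`, a bookkeeping tag.
#' @return An object of class `mode_spectrum`: list with `values` (ascending),
#'   `vectors` (columns matching `values`), `n_zero`, `zero_tolerance`, `kind`.
#' @export
decompose_modes <- function(matrix, zero_tolerance = 1e-8, kind = "gnm") {
  if (!isSymmetric(unname(matrix), tol = 1e-8)) {
    stop("matrix must be symmetric")
  }
  e <- eigen((matrix + t(matrix)) / 2, symmetric = TRUE)
  ord <- order(e$values)
  values <- e$values[ord]
  vectors <- e$vectors[, ord, drop = FALSE]
  tol_abs <- zero_tolerance * max(abs(values), 0)
  if (any(values < -max(tol_abs, zero_tolerance))) {
    stop("matrix is not positive semidefinite (min eigenvalue ",
         format(min(values)), ")")
  }
  n_zero <- sum(values <= tol_abs)
  structure(list(values = values, vectors = vectors, n_zero = n_zero,
                 zero_tolerance = zero_tolerance, kind = kind),
            class = "mode_spectrum")
}

#' @export
print.mode_spectrum <- function(x, ...) {
  nz <- length(x$values) - x$n_zero
  cat(sprintf("Mode spectrum (%s): %d modes, %d zero + %d nonzero\n",
              x$kind, length(x$values), x$n_zero, nz))
  if (nz > 0) {
    cat(sprintf("  nonzero eigenvalues: %.4g .. %.4g\n",
                x$values[x$n_zero + 1], max(x$values)))
  }
  invisible(x)
}

#' Moore-Penrose pseudo-inverse from a mode spectrum
#'
#' Sums `1/lambda_k u_k u_k^T` over the nonzero modes only, i.e. the inverse
#' on the orthogonal complement of the zero-mode space. Optionally restricted
#' to an explicit subset of nonzero modes (1 = slowest nonzero).
#'
#' @param spectrum a `mode_spectrum`.
#' @param modes `NULL` for all nonzero modes, or integer indices among the
#'   nonzero modes, counted from the smallest nonzero eigenvalue.
#' @return Symmetric numeric matrix of the same size as the input matrix.
#' @export
pseudo_inverse <- function(spectrum, modes = NULL) {
  stopifnot(inherits(spectrum, "mode_spectrum"))
  nz_idx <- nonzero_mode_index(spectrum, modes)
  if (length(nz_idx) == 0L) {
    n <- nrow(spectrum$vectors)
    return(matrix(0, n, n))
  }
  U <- spectrum$vectors[, nz_idx, drop = FALSE]
  U %*% (t(U) / spectrum$values[nz_idx])
}

# indices into the full spectrum for a requested nonzero-mode subset
nonzero_mode_index <- function(spectrum, modes = NULL) {
  all_nz <- seq_along(spectrum$values)[-seq_len(spectrum$n_zero)]
  if (spectrum$n_zero == 0L) all_nz <- seq_along(spectrum$values)
  if (is.null(modes)) return(all_nz)
  modes <- as.integer(modes)
  if (any(modes < 1L) || any(modes > length(all_nz))) {
    stop("mode subset out of range; ", length(all_nz), " nonzero modes available")
  }
  all_nz[modes]
}
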