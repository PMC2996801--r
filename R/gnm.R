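#' Fit a Gaussian network model
#'
#' Builds the contact topology of a coarse-grained structure at the given
#' cutoff, assembles the Kirchhoff matrix (identical spring constant for all
#' contacts), decomposes it, and — if experimental B-factors are supplied —
#' fits the single free parameter of the model, the scale
#' \eqn{k_B T / \gamma}, by least squares against the predicted B-factors.
#'
#' The model: node fluctuations obey
#' \eqn{\langle \Delta R_i \cdot \Delta R_j \rangle = (3 k_B T/\gamma)\,
#' [\Gamma^{-1}]_{ij}} where \eqn{\Gamma^{-1}} is the pseudo-inverse of the
#' Kirchhoff matrix over its nonzero modes, and predicted B-factors are
#' \eqn{B_i = (8\pi^2/3) \langle \Delta R_i^2 \rangle}. Metal nodes
#' participate in the network but are excluded from the B-factor fit (there
#' is no experimental C-alpha B-factor for them).
#'
#' @param structure a [cg_structure()].
#' @param cutoff contact cutoff in Angstrom (default 7.3).
#' @param bfactors optional experimental B-factors for the protein nodes: an
#'   [read_experimental_bfactors()] object or a numeric vector (Angstrom^2).
#' @param zero_tolerance relative eigenvalue tolerance for zero modes.
#' @return An object of class `gnm`: list with the `structure`, `topology`,
#'   `kirchhoff` matrix, mode `spectrum`, pseudo-inverse `pinv`, its diagonal
#'   `shape`, and (when `bfactors` is given) the `fit` (`kt_over_gamma`,
#'   `correlation`, `experimental`).
#' @seealso [mean_square_fluctuations()], [cross_correlation_map()],
#'   [mode_shape_profile()], [distance_fluctuation()], [unfold()]
#' @examples
#' s <- toy_zinc_finger()
#' b <- simulate_bfactors(s, kt_over_gamma = 0.068, noise_sd = 0.2, seed = 1)
#' m <- gnm(s, cutoff = 7.3, bfactors = b)
#' coef(m)
#' @export
gnm <- function(structure, cutoff = 7.3, bfactors = NULL,
                zero_tolerance = 1e-8) {
  topology <- build_topology(structure, cutoff)
  K <- kirchhoff_matrix(topology)
  spectrum <- decompose_modes(K, zero_tolerance, kind = "gnm")
  pinv <- pseudo_inverse(spectrum)
  shape <- diag(pinv)
  fit <- NULL
  if (!is.null(bfactors)) {
    fit <- fit_scale(shape[!structure$is_metal], bfactors)
  }
  structure(list(structure = structure, topology = topology, kirchhoff = K,
                 spectrum = spectrum, pinv = pinv, shape = shape, fit = fit,
                 cutoff = cutoff),
            class = "gnm")
}

#' @export
print.gnm <- function(x, ...) {
  cat(sprintf("Gaussian network model: %d nodes, cutoff %.2f A\n",
              x$topology$n_nodes, x$cutoff))
  cat(sprintf("  contacts: %d covalent, %d noncovalent; zero modes: %d\n",
              nrow(x$topology$covalent), nrow(x$topology$noncovalent),
              x$spectrum$n_zero))
  if (!is.null(x$fit)) {
    cat(sprintf("  fitted kT/gamma = %.4g A^2, B-factor correlation = %.3f\n",
                x$fit$kt_over_gamma, x$fit$correlation))
  }
  invisible(x)
}

#' @export
summary.gnm <- function(object, ...) {
  nz <- object$spectrum$values[nonzero_mode_index(object$spectrum)]
  out <- list(
    n_nodes = object$topology$n_nodes,
    n_metal = sum(object$structure$is_metal),
    cutoff = object$cutoff,
    n_covalent = nrow(object$topology$covalent),
    n_noncovalent = nrow(object$topology$noncovalent),
    n_zero_modes = object$spectrum$n_zero,
    eigenvalue_range = range(nz),
    fit = object$fit
  )
  class(out) <- "summary.gnm"
  out
}

#' @export
print.summary.gnm <- function(x, ...) {
  cat("Gaussian network model\n")
  cat(sprintf("  nodes: %d (%d metal), cutoff %.2f A\n",
              x$n_nodes, x$n_metal, x$cutoff))
  cat(sprintf("  contacts: %d covalent + %d noncovalent\n",
              x$n_covalent, x$n_noncovalent))
  cat(sprintf("  zero modes: %d; nonzero eigenvalues %.4g .. %.4g\n",
              x$n_zero_modes, x$eigenvalue_range[1], x$eigenvalue_range[2]))
  if (!is.null(x$fit)) {
    cat(sprintf("  kT/gamma = %.4g A^2 (B-factor Pearson r = %.3f, source %s)\n",
                x$fit$kt_over_gamma, x$fit$correlation,
                x$fit$source %||% "numeric"))
  } else {
    cat("  no experimental B-factors supplied; scale not fitted\n")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
coef.gnm <- function(object, ...) {
  c(kt_over_gamma = if (is.null(object$fit)) NA_real_ else
    object$fit$kt_over_gamma)
}

#' @export
fitted.gnm <- function(object, ...) {
  if (is.null(object$fit)) {
    stop("no experimental B-factors were supplied; nothing was fitted")
  }
  prot <- !object$structure$is_metal
  8 * pi^2 * object$fit$kt_over_gamma * object$shape[prot]
}

#' @export
residuals.gnm <- function(object, ...) {
  object$fit$experimental - fitted(object)
}

#' Plot method for fitted Gaussian network models
#'
#' @param x a `gnm` object.
#' @param type `"bfactors"` (experimental vs predicted per residue, requires a
#'   fit), `"modes"` (slowest and fastest mode-shape profiles) or
#'   `"correlation"` (cross-correlation map as an image).
#' @param k number of modes averaged in the `"modes"` profiles.
#' @param ... passed to the underlying plotting call.
#' @return `x`, invisibly.
#' @export
plot.gnm <- function(x, type = c("bfactors", "modes", "correlation"), k = 1,
                     ...) {
  type <- match.arg(type)
  if (type == "bfactors") {
    pred <- fitted(x)
    obs <- x$fit$experimental
    matplot(seq_along(obs), cbind(obs, pred), type = "l", lty = c(1, 2),
            col = c("grey50", "black"), xlab = "residue",
            ylab = expression(B ~ (ring(A)^2)), ...)
    legend("topleft", c("experimental", "GNM"), lty = c(1, 2),
           col = c("grey50", "black"), bty = "n")
  } else if (type == "modes") {
    slow <- mode_shape_profile(x, "slowest", k)
    fast <- mode_shape_profile(x, "fastest", k)
    matplot(seq_along(slow), cbind(slow, fast), type = "l", lty = c(1, 2),
            col = c("black", "grey40"), xlab = "node",
            ylab = "mode shape (squared amplitude)", ...)
    legend("topleft", paste(c("slowest", "fastest"), k), lty = c(1, 2),
           col = c("black", "grey40"), bty = "n")
  } else {
    C <- cross_correlation_map(x)
    n <- nrow(C)
    image(seq_len(n), seq_len(n), C, zlim = c(-1, 1),
          col = gray.colors_safe(), xlab = "node", ylab = "node", ...)
  }
  invisible(x)
}

gray.colors_safe <- function() grDevices::gray(seq(0, 1, length.out = 64))

#' Mean-square fluctuations from a GNM
#'
#' \eqn{\langle \Delta R_i^2 \rangle = 3 (k_B T/\gamma) [\Gamma^+]_{ii}}.
#'
#' @param x a `gnm` object or a `mode_spectrum` of kind `"gnm"`.
#' @param kt_over_gamma the fluctuation scale in Angstrom^2 (default: the
#'   fitted value for a fitted `gnm`, otherwise 1).
#' @return Numeric vector of per-node mean-square fluctuations (Angstrom^2).
#' @export
mean_square_fluctuations <- function(x, kt_over_gamma = NULL) {
  shape <- gnm_shape(x)
  if (is.null(kt_over_gamma)) {
    kt_over_gamma <- if (inherits(x, "gnm") && !is.null(x$fit)) {
      x$fit$kt_over_gamma
    } else 1
  }
  if (kt_over_gamma < 0) stop("'kt_over_gamma' must be nonnegative")
  3 * kt_over_gamma * shape
}

gnm_shape <- function(x) {
  if (inherits(x, "gnm")) return(x$shape)
  if (inherits(x, "mode_spectrum")) return(diag(pseudo_inverse(x)))
  stop("'x' must be a 'gnm' or 'mode_spectrum' object")
}

gnm_spectrum <- function(x) {
  if (inherits(x, "gnm")) return(x$spectrum)
  if (inherits(x, "mode_spectrum")) return(x)
  stop("'x' must be a 'gnm' or 'mode_spectrum' object")
}

gnm_pinv <- function(x, modes = NULL) {
  if (inherits(x, "gnm") && is.null(modes)) return(x$pinv)
  pseudo_inverse(gnm_spectrum(x), modes)
}

#' Predicted B-factors from mean-square fluctuations
#'
#' \eqn{B_i = (8\pi^2/3) \langle \Delta R_i^2 \rangle}.
#'
#' @param msf numeric vector of mean-square fluctuations (Angstrom^2).
#' @return Numeric vector of B-factors (Angstrom^2).
#' @export
predicted_bfactors <- function(msf) {
  msf <- as.numeric(msf)
  if (any(msf < 0)) stop("mean-square fluctuations must be nonnegative")
  (8 * pi^2 / 3) * msf
}

#' Fit the GNM fluctuation scale against experimental B-factors
#'
#' The only free parameter of the GNM is the spring constant, entering all
#' fluctuations through the scale \eqn{k_B T/\gamma}. It is obtained by
#' least-squares regression through the origin of the experimental B-factors
#' on the predicted shape \eqn{8\pi^2 [\Gamma^+]_{ii}}. The reported Pearson
#' correlation between experiment and shape is scale-invariant, so it does
#' not depend on how the scale itself is estimated.
#'
#' @param shape per-node \eqn{[\Gamma^+]_{ii}} for the protein nodes (metal
#'   nodes are excluded from the fit).
#' @param experimental an `experimental_bfactors` object or numeric vector of
#'   the same length (Angstrom^2).
#' @return List with `kt_over_gamma` (Angstrom^2), `correlation` (Pearson),
#'   `experimental` (the values used) and `source`.
#' @examples
#' shape <- c(5, 2, 5) / 9
#' fit_scale(shape, 8 * pi^2 * 0.05 * shape)  # exact recovery: 0.05, r = 1
#' @export
fit_scale <- function(shape, experimental) {
  source <- if (inherits(experimental, "experimental_bfactors")) {
    experimental$source
  } else "numeric"
  b <- unclass_bfactors(experimental)
  shape <- as.numeric(shape)
  if (length(b) != length(shape)) {
    stop("experimental B-factors (", length(b), ") and predicted shape (",
         length(shape), ") differ in length")
  }
  if (stats::var(b) == 0) {
    stop("experimental B-factors have zero variance; the scale cannot be fitted")
  }
  x <- 8 * pi^2 * shape
  kt <- sum(b * x) / sum(x * x)
  list(kt_over_gamma = kt, correlation = stats::cor(b, shape),
       experimental = b, source = source)
}

#' Normalized cross-correlation map of residue fluctuations
#'
#' \eqn{C_{ij} = \langle \Delta R_i \cdot \Delta R_j \rangle /
#' (\langle \Delta R_i^2 \rangle \langle \Delta R_j^2 \rangle)^{1/2}},
#' computed from the (optionally mode-restricted) pseudo-inverse. Entries lie
#' in \[-1, 1\] with unit diagonal. A node with zero mean-square fluctuation
#' (e.g. one isolated during unfolding) gets zero off-diagonal entries and
#' `C_ii = 1` by convention.
#'
#' @param x a `gnm` object or a GNM `mode_spectrum`.
#' @param modes `NULL` for all nonzero modes, or indices among the nonzero
#'   modes (1 = slowest nonzero).
#' @return Symmetric numeric matrix with unit diagonal.
#' @export
cross_correlation_map <- function(x, modes = NULL) {
  G <- gnm_pinv(x, modes)
  d <- diag(G)
  tol <- 1e-12 * max(d, 1e-300)
  live <- d > tol
  C <- matrix(0, nrow(G), ncol(G))
  if (any(live)) {
    s <- sqrt(d[live])
    C[live, live] <- G[live, live] / tcrossprod(s)
  }
  diag(C) <- 1
  C
}

#' Mode-shape profile (slow or fast modes)
#'
#' The per-node profile is the unweighted mean of squared eigenvector
#' components over the selected nonzero modes; it sums to 1 over nodes. Slow
#' modes capture collective functional motions; fast modes flag kinetically
#' key, tightly constrained residues. An eigenvalue-weighted variant
#' (weights \eqn{1/\lambda_k}, normalized) is available via `weighted`.
#'
#' @param x a `gnm` object or GNM `mode_spectrum`.
#' @param which `"slowest"` or `"fastest"`.
#' @param k number of nonzero modes to average (slowest-k counts up from the
#'   smallest nonzero eigenvalue, fastest-k down from the largest).
#' @param weighted if `TRUE`, weight modes by inverse eigenvalue.
#' @return Numeric per-node profile summing to 1.
#' @export
mode_shape_profile <- function(x, which = c("slowest", "fastest"), k = 1,
                               weighted = FALSE) {
  which <- match.arg(which)
  sp <- gnm_spectrum(x)
  nz <- nonzero_mode_index(sp)
  k <- as.integer(k)
  if (k < 1L || k > length(nz)) {
    stop("'k' must be between 1 and the number of nonzero modes (",
         length(nz), ")")
  }
  sel <- if (which == "slowest") nz[seq_len(k)] else nz[length(nz) - k + seq_len(k)]
  U2 <- sp$vectors[, sel, drop = FALSE]^2
  if (weighted) {
    w <- 1 / sp$values[sel]
    drop(U2 %*% (w / sum(w)))
  } else {
    rowMeans(U2)
  }
}

#' Mean-square fluctuation of an inter-node distance
#'
#' \eqn{\langle (\Delta R_{ij})^2 \rangle = 3 (k_B T/\gamma)
#' ([\Gamma^+]_{ii} + [\Gamma^+]_{jj} - 2 [\Gamma^+]_{ij})}: the fluctuation
#' of the separation vector between nodes i and j about its equilibrium
#' value. This is the quantity that drives contact breaking in [unfold()].
#'
#' @param x a `gnm` object or GNM `mode_spectrum`.
#' @param i,j node indices (equal-length vectors are accepted).
#' @param kt_over_gamma fluctuation scale (Angstrom^2), default 1.
#' @return Numeric vector of distance fluctuations (Angstrom^2); symmetric in
#'   (i, j), zero for i = j.
#' @export
distance_fluctuation <- function(x, i, j, kt_over_gamma = 1) {
  G <- gnm_pinv(x)
  i <- as.integer(i); j <- as.integer(j)
  stopifnot(length(i) == length(j), all(i >= 1), all(j >= 1),
            all(i <= nrow(G)), all(j <= nrow(G)))
  3 * kt_over_gamma * (G[cbind(i, i)] + G[cbind(j, j)] - 2 * G[cbind(i, j)])
}
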