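#' Build the spring-network topology of a structure
#'
#' Any two distinct nodes closer than the cutoff are in contact. Consecutive
#' protein nodes of the same chain are classified as covalent neighbours and
#' are always connected, even if their distance exceeds the cutoff (chain
#' connectivity must survive unfolding). All other contacts — including every
#' metal-residue bond — are noncovalent and thus breakable by [unfold()].
#'
#' @param structure a [cg_structure()].
#' @param cutoff contact cutoff distance in Angstrom (default 7.3).
#' @return An object of class `contact_topology`: list with `n_nodes`,
#'   integer pair matrices `covalent` and `noncovalent` (i < j, lexicographic
#'   order), and `cutoff`.
#' @examples
#' build_topology(toy_zinc_finger(), cutoff = 7.3)
#' @export
build_topology <- function(structure, cutoff = 7.3) {
  stopifnot(inherits(structure, "cg_structure"), cutoff > 0)
  n <- nrow(structure$xyz)
  d <- as.matrix(stats::dist(structure$xyz))

  prot <- which(!structure$is_metal)
  cov <- NULL
  if (length(prot) >= 2L) {
    i <- prot[-length(prot)]
    j <- prot[-1]
    same_chain <- structure$labels$chain[i] == structure$labels$chain[j]
    cov <- cbind(i[same_chain], j[same_chain])
  }
  cov <- canonical_pairs(cov)

  within <- which(upper.tri(d) & d <= cutoff, arr.ind = TRUE)
  all_pairs <- canonical_pairs(within)
  noncov <- all_pairs[!(pair_key(all_pairs) %in% pair_key(cov)), , drop = FALSE]

  new_contact_topology(n, cov, noncov, cutoff)
}

new_contact_topology <- function(n_nodes, covalent, noncovalent, cutoff) {
  covalent <- canonical_pairs(covalent)
  noncovalent <- canonical_pairs(noncovalent)
  if (length(intersect(pair_key(covalent), pair_key(noncovalent)))) {
    stop("covalent and noncovalent pair sets must be disjoint")
  }
  idx <- c(covalent, noncovalent)
  if (length(idx) && (min(idx) < 1L || max(idx) > n_nodes)) {
    stop("pair indices out of range")
  }
  structure(list(n_nodes = as.integer(n_nodes), covalent = covalent,
                 noncovalent = noncovalent, cutoff = cutoff),
            class = "contact_topology")
}

#' @export
print.contact_topology <- function(x, ...) {
  cat(sprintf("Contact topology: %d nodes, %d covalent + %d noncovalent contacts (cutoff %.2f A)\n",
              x$n_nodes, nrow(x$covalent), nrow(x$noncovalent), x$cutoff))
  invisible(x)
}

#' Kirchhoff (connectivity) matrix of a topology
#'
#' Off-diagonal entries are -1 for every contact (covalent or noncovalent) and
#' 0 otherwise; the diagonal holds the node degree, so every row sums to zero.
#'
#' @param topology a `contact_topology` from [build_topology()].
#' @return Symmetric `n x n` numeric matrix.
#' @export
kirchhoff_matrix <- function(topology) {
  stopifnot(inherits(topology, "contact_topology"))
  n <- topology$n_nodes
  K <- matrix(0, n, n)
  pairs <- rbind(topology$covalent, topology$noncovalent)
  if (nrow(pairs)) {
    K[pairs] <- -1
    K[pairs[, c(2, 1), drop = FALSE]] <- -1
  }
  diag(K) <- -rowSums(K)
  K
}

#' Contact map of a topology
#'
#' @param topology a `contact_topology`.
#' @return Symmetric logical `n x n` matrix; entry `[i, j]` is `TRUE` iff the
#'   pair is a current contact (covalent or noncovalent). The diagonal is
#'   `FALSE`.
#' @seealso [contact_edges()] for the equivalent edge-list form.
#' @export
contact_map <- function(topology) {
  stopifnot(inherits(topology, "contact_topology"))
  n <- topology$n_nodes
  M <- matrix(FALSE, n, n)
  pairs <- rbind(topology$covalent, topology$noncovalent)
  if (nrow(pairs)) {
    M[pairs] <- TRUE
    M[pairs[, c(2, 1), drop = FALSE]] <- TRUE
  }
  M
}

#' Contact edge list of a topology
#'
#' @param topology a `contact_topology`.
#' @return Data frame with columns `i`, `j` (i < j, lexicographic order) and
#'   `covalent` (logical).
#' @export
contact_edges <- function(topology) {
  stopifnot(inherits(topology, "contact_topology"))
  pairs <- rbind(topology$covalent, topology$noncovalent)
  covalent <- rep(c(TRUE, FALSE),
                  c(nrow(topology$covalent), nrow(topology$noncovalent)))
  ord <- order(pairs[, 1], pairs[, 2])
  data.frame(i = pairs[ord, 1], j = pairs[ord, 2], covalent = covalent[ord])
}
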