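#' Iterative contact-breaking unfolding simulation
#'
#' Mimics thermal unfolding as a sequence of quasi-equilibrium network
#' states: at each step the mean-square distance fluctuation of every current
#' noncovalent contact is computed from the current network's Kirchhoff
#' pseudo-inverse, the contact with the largest fluctuation is broken, the
#' network is rebuilt, and the scan repeats until no noncovalent contact
#' remains. Covalent (chain-neighbour) springs are never broken, so the
#' protein backbone stays connected throughout; a metal node that loses all
#' its contacts becomes an isolated component and is inert thereafter (it
#' only adds a zero mode).
#'
#' Ties within a relative tolerance of 1e-10 are broken deterministically in
#' favour of the lexicographically smallest pair (i, j). The fluctuation
#' scale `kt_over_gamma` multiplies all candidates uniformly, so it cannot
#' change the break order.
#'
#' @param structure a [cg_structure()].
#' @param cutoff GNM contact cutoff in Angstrom (default 7.3).
#' @param kt_over_gamma fluctuation scale recorded with the logged values.
#' @param zero_tolerance relative eigenvalue tolerance for zero modes.
#' @return An object of class `unfolding`: list with the `structure`, the
#'   `initial` contact topology, and `events` — a data frame with one row per
#'   broken contact: `step`, node indices `i`, `j`, the distance
#'   `fluctuation` (Angstrom^2) at break time, `lnnc` (loss number of
#'   noncovalent contacts, equal to `step`), and `remaining` noncovalent
#'   contacts.
#' @seealso [snapshot_topology()], [bond_break_order()],
#'   [snapshot_cross_correlation()]
#' @examples
#' tr <- unfold(toy_zinc_finger())
#' head(tr$events)
#' @export
unfold <- function(structure, cutoff = 7.3, kt_over_gamma = 1,
                   zero_tolerance = 1e-8) {
  topo <- build_topology(structure, cutoff)
  ncv <- topo$noncovalent
  E <- nrow(ncv)
  alive <- rep(TRUE, E)
  events <- data.frame(step = integer(E), i = integer(E), j = integer(E),
                       fluctuation = numeric(E), lnnc = integer(E),
                       remaining = integer(E))
  for (step in seq_len(E)) {
    cur <- new_contact_topology(topo$n_nodes, topo$covalent,
                                ncv[alive, , drop = FALSE], cutoff)
    sp <- decompose_modes(kirchhoff_matrix(cur), zero_tolerance, kind = "gnm")
    G <- pseudo_inverse(sp)
    cand <- which(alive)
    i <- ncv[cand, 1]; j <- ncv[cand, 2]
    f <- 3 * kt_over_gamma *
      (G[cbind(i, i)] + G[cbind(j, j)] - 2 * G[cbind(i, j)])
    fmax <- max(f)
    top <- which(f >= fmax - 1e-10 * abs(fmax))
    pick <- top[order(i[top], j[top])[1]]
    sel <- cand[pick]
    alive[sel] <- FALSE
    events[step, ] <- list(step, ncv[sel, 1], ncv[sel, 2], f[pick], step,
                           E - step)
  }
  structure(list(structure = structure, initial = topo, events = events,
                 cutoff = cutoff, kt_over_gamma = kt_over_gamma,
                 zero_tolerance = zero_tolerance),
            class = "unfolding")
}

#' @export
print.unfolding <- function(x, ...) {
  E <- nrow(x$events)
  cat(sprintf("Unfolding trajectory: %d contact-breaking events (cutoff %.2f A)\n",
              E, x$cutoff))
  if (E > 0) {
    cat(sprintf("  first break: (%d, %d), fluctuation %.4g A^2\n",
                x$events$i[1], x$events$j[1], x$events$fluctuation[1]))
    cat(sprintf("  last break:  (%d, %d), fluctuation %.4g A^2\n",
                x$events$i[E], x$events$j[E], x$events$fluctuation[E]))
  }
  invisible(x)
}

#' @export
summary.unfolding <- function(object, ...) {
  ev <- object$events
  met <- which(object$structure$is_metal)
  metal_events <- ev[ev$i %in% met | ev$j %in% met, , drop = FALSE]
  out <- list(n_events = nrow(ev),
              n_covalent = nrow(object$initial$covalent),
              cutoff = object$cutoff,
              first = ev[seq_len(min(3, nrow(ev))), ],
              metal_events = metal_events)
  class(out) <- "summary.unfolding"
  out
}

#' @export
print.summary.unfolding <- function(x, ...) {
  cat(sprintf("Unfolding: %d noncovalent contacts broken (%d covalent kept)\n",
              x$n_events, x$n_covalent))
  cat("first events:\n")
  print(x$first, row.names = FALSE)
  if (nrow(x$metal_events)) {
    cat("metal-contact break events:\n")
    print(x$metal_events, row.names = FALSE)
  }
  invisible(x)
}

#' @export
as.data.frame.unfolding <- function(x, ...) x$events

#' Plot an unfolding trajectory
#'
#' Maximal distance fluctuation at each break step.
#'
#' @param x an `unfolding` object.
#' @param ... passed to `plot`.
#' @return `x`, invisibly.
#' @export
plot.unfolding <- function(x, ...) {
  plot(x$events$step, x$events$fluctuation, type = "l",
       xlab = "LNNC (contacts broken)",
       ylab = expression("max distance fluctuation" ~ (ring(A)^2)), ...)
  invisible(x)
}

#' Network topology after a given number of broken contacts
#'
#' @param trajectory an [unfold()] result.
#' @param lnnc number of noncovalent contacts already lost (0 = native state,
#'   `nrow(trajectory$events)` = fully unfolded).
#' @return A `contact_topology`: the initial topology minus the first `lnnc`
#'   broken pairs.
#' @export
snapshot_topology <- function(trajectory, lnnc) {
  stopifnot(inherits(trajectory, "unfolding"))
  E <- nrow(trajectory$events)
  lnnc <- as.integer(lnnc)
  if (lnnc < 0L || lnnc > E) {
    stop("'lnnc' must be between 0 and the number of events (", E, ")")
  }
  ncv <- trajectory$initial$noncovalent
  if (lnnc > 0L) {
    broken <- pair_key(as.matrix(trajectory$events[seq_len(lnnc), c("i", "j")]))
    ncv <- ncv[!(pair_key(ncv) %in% broken), , drop = FALSE]
  }
  new_contact_topology(trajectory$initial$n_nodes,
                       trajectory$initial$covalent, ncv,
                       trajectory$initial$cutoff)
}

#' Break steps of selected contacts
#'
#' @param trajectory an [unfold()] result.
#' @param pairs 2-column matrix (or a list of length-2 vectors) of node index
#'   pairs; each must be a noncovalent contact of the initial topology
#'   (querying a covalent pair, which can never break, is an error).
#' @return Data frame with columns `i`, `j`, `step`, sorted by break step.
#' @examples
#' s <- toy_zinc_finger()
#' tr <- unfold(s)
#' zn <- n_nodes(s)
#' bond_break_order(tr, cbind(c(5, 10, 23, 27), zn))
#' @export
bond_break_order <- function(trajectory, pairs) {
  stopifnot(inherits(trajectory, "unfolding"))
  if (is.list(pairs) && !is.data.frame(pairs)) {
    pairs <- do.call(rbind, pairs)
  }
  p <- canonical_pairs(as.matrix(pairs))
  keys <- pair_key(p)
  cov_keys <- pair_key(trajectory$initial$covalent)
  if (any(keys %in% cov_keys)) {
    stop("covalent pair(s) queried: ",
         paste(keys[keys %in% cov_keys], collapse = ", "),
         "; covalent contacts never break")
  }
  ev_keys <- pair_key(as.matrix(trajectory$events[, c("i", "j")]))
  hit <- match(keys, ev_keys)
  if (anyNA(hit)) {
    stop("pair(s) not among the initial noncovalent contacts: ",
         paste(keys[is.na(hit)], collapse = ", "))
  }
  out <- data.frame(i = p[, 1], j = p[, 2],
                    step = trajectory$events$step[hit])
  out[order(out$step), , drop = FALSE]
}

#' Cross-correlation map of an unfolding snapshot
#'
#' Rebuilds the Kirchhoff matrix of the snapshot topology and computes the
#' normalized cross-correlation map over all nonzero modes. Nodes isolated by
#' unfolding have zero fluctuation: their off-diagonal entries are 0 and the
#' diagonal is 1 by convention. The fluctuation scale cancels in the
#' normalization.
#'
#' @inheritParams snapshot_topology
#' @param kt_over_gamma accepted for symmetry with [distance_fluctuation()];
#'   it cancels in the normalized map.
#' @return Symmetric matrix with unit diagonal, entries in \[-1, 1\].
#' @export
snapshot_cross_correlation <- function(trajectory, lnnc, kt_over_gamma = 1) {
  topo <- snapshot_topology(trajectory, lnnc)
  sp <- decompose_modes(kirchhoff_matrix(topo), trajectory$zero_tolerance,
                        kind = "gnm")
  cross_correlation_map(sp)
}
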