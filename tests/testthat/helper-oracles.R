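# Independent oracles: every routine here recomputes quantities from first
# principles (brute-force loops, SVD, finite differences) without touching the
# package's own linear-algebra paths.

# Kirchhoff matrix by exhaustive double loop over node pairs
oracle_kirchhoff <- function(xyz, cutoff, covalent = NULL, noncovalent = NULL) {
  n <- nrow(xyz)
  K <- matrix(0, n, n)
  if (is.null(covalent) && is.null(noncovalent)) {
    for (i in 1:n) for (j in 1:n) {
      if (i == j) next
      if (sqrt(sum((xyz[i, ] - xyz[j, ])^2)) <= cutoff) K[i, j] <- -1
    }
  } else {
    pairs <- rbind(covalent, noncovalent)
    for (r in seq_len(nrow(pairs))) {
      K[pairs[r, 1], pairs[r, 2]] <- -1
      K[pairs[r, 2], pairs[r, 1]] <- -1
    }
  }
  diag(K) <- 0
  diag(K) <- -rowSums(K)
  K
}

# Kirchhoff for a structure honoring the chain rule (consecutive protein
# nodes always bonded), independent of build_topology()
oracle_kirchhoff_structure <- function(structure, cutoff) {
  K <- oracle_kirchhoff(structure$xyz, cutoff)
  prot <- which(!structure$is_metal)
  for (k in seq_len(length(prot) - 1)) {
    i <- prot[k]; j <- prot[k + 1]
    if (structure$labels$chain[i] == structure$labels$chain[j]) {
      K[i, j] <- K[j, i] <- -1
    }
  }
  diag(K) <- 0
  diag(K) <- -rowSums(K)
  K
}

# Moore-Penrose pseudo-inverse via SVD
svd_pinv <- function(M, tol = 1e-8) {
  s <- svd(M)
  keep <- s$d > tol * max(s$d)
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

# connected components by breadth-first search on the contact graph
oracle_components <- function(K) {
  n <- nrow(K)
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (start in 1:n) {
    if (!is.na(comp[start])) next
    cid <- cid + 1L
    queue <- start
    comp[start] <- cid
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(K[v, ] != 0 & seq_len(n) != v & is.na(comp))
      comp[nb] <- cid
      queue <- c(queue, nb)
    }
  }
  cid
}

# random connected topology: spanning path plus random extra edges
random_topology <- function(n, seed, p_extra = 0.25) {
  set.seed(seed)
  cov <- cbind(1:(n - 1), 2:n)
  extra <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  extra <- extra[extra[, 2] - extra[, 1] > 1, , drop = FALSE]
  keep <- runif(nrow(extra)) < p_extra
  list(covalent = cov, noncovalent = extra[keep, , drop = FALSE], n = n)
}

# full from-scratch unfolding reimplementation: rebuilds the Kirchhoff matrix
# each step with the double loop, takes the SVD pseudo-inverse, and scans all
# surviving noncovalent pairs exhaustively
oracle_unfold <- function(structure, cutoff) {
  K0 <- oracle_kirchhoff_structure(structure, cutoff)
  prot <- which(!structure$is_metal)
  cov <- matrix(0L, 0, 2)
  for (k in seq_len(length(prot) - 1)) {
    cov <- rbind(cov, c(prot[k], prot[k + 1]))
  }
  all_pairs <- which(upper.tri(K0) & K0 != 0, arr.ind = TRUE)
  covkey <- paste(cov[, 1], cov[, 2])
  ncv <- all_pairs[!(paste(all_pairs[, 1], all_pairs[, 2]) %in% covkey), ,
                   drop = FALSE]
  events <- NULL
  while (nrow(ncv) > 0) {
    K <- oracle_kirchhoff(structure$xyz, cutoff, cov, ncv)
    G <- svd_pinv(K)
    f <- numeric(nrow(ncv))
    for (r in seq_len(nrow(ncv))) {
      i <- ncv[r, 1]; j <- ncv[r, 2]
      f[r] <- 3 * (G[i, i] + G[j, j] - 2 * G[i, j])
    }
    fmax <- max(f)
    top <- which(f >= fmax - 1e-10 * abs(fmax))
    pick <- top[order(ncv[top, 1], ncv[top, 2])[1]]
    events <- rbind(events, c(ncv[pick, 1], ncv[pick, 2], f[pick]))
    ncv <- ncv[-pick, , drop = FALSE]
  }
  colnames(events) <- c("i", "j", "fluctuation")
  events
}

# numeric Hessian of the pairwise-spring ANM potential at equilibrium
fd_hessian <- function(xyz, cutoff, gamma = 1, h = 1e-4) {
  n <- nrow(xyz)
  d0 <- as.matrix(dist(xyz))
  in_cut <- d0 <= cutoff & upper.tri(d0)
  V <- function(x) {
    m <- matrix(x, n, 3, byrow = TRUE)
    dd <- as.matrix(dist(m))
    0.5 * gamma * sum((dd[in_cut] - d0[in_cut])^2)
  }
  x0 <- as.vector(t(xyz))
  m <- length(x0)
  H <- matrix(0, m, m)
  for (a in 1:m) {
    for (b in a:m) {
      ea <- eb <- numeric(m)
      ea[a] <- h; eb[b] <- h
      H[a, b] <- H[b, a] <-
        (V(x0 + ea + eb) - V(x0 + ea - eb) -
           V(x0 - ea + eb) + V(x0 - ea - eb)) / (4 * h^2)
    }
  }
  H
}

random_cloud <- function(n, seed, spread = 6) {
  set.seed(seed)
  matrix(runif(3 * n, 0, spread), n, 3)
}

# independent ensemble B-factor oracle: own Kabsch superposition + per-residue
# positional variance (n-1 denominator), B = (8 pi^2 / 3) * variance
oracle_ensemble_bfactors <- function(models) {
  ref <- models[[1]]
  fit_one <- function(m) {
    cm <- colMeans(m); cr <- colMeans(ref)
    A <- t(sweep(m, 2, cm)) %*% sweep(ref, 2, cr)
    s <- svd(A)
    d <- sign(det(s$v %*% t(s$u)))
    R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
    sweep(sweep(m, 2, cm) %*% t(R), 2, cr, "+")
  }
  fitted <- lapply(models, fit_one)
  n <- nrow(ref)
  vapply(seq_len(n), function(i) {
    P <- do.call(rbind, lapply(fitted, function(m) m[i, ]))
    (8 * pi^2 / 3) * sum(apply(P, 2, var))
  }, numeric(1))
}
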