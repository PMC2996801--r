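#' Specify a synthetic coarse-grained chain
#'
#' Describes a toy fold as an ordered list of secondary-structure segments
#' plus an optional pseudo-metal node bound to four designated ligand
#' residues. [make_chain()] turns the specification into coordinates.
#'
#' @param segments named numeric vector; names among `"helix"`, `"strand"`,
#'   `"loop"`, `"hairpin"`, values are segment lengths in residues (duplicated
#'   names are allowed, e.g. `c(hairpin = 12, loop = 2, helix = 12, loop = 5)`).
#' @param metal optional integer vector of 4 distinct ligand residue indices;
#'   a pseudo-metal node is placed at the centroid of their C-alpha positions.
#' @param seed integer seed used for any stochastic element of the build
#'   (coordinate jitter); the deterministic geometry does not consume it.
#' @return An object of class `chain_spec`.
#' @export
chain_spec <- function(segments, metal = NULL, seed = 1L) {
  kinds <- names(segments)
  if (is.null(kinds) || !all(kinds %in% c("helix", "strand", "loop", "hairpin"))) {
    stop("'segments' must be a named vector with names among ",
         "helix/strand/loop/hairpin")
  }
  lens <- as.integer(segments)
  if (any(lens < 1L)) stop("segment lengths must be positive")
  if (any(kinds == "hairpin" & lens < 4L)) {
    stop("a hairpin segment needs at least 4 residues")
  }
  n <- sum(lens)
  if (!is.null(metal)) {
    metal <- as.integer(metal)
    if (length(metal) != 4L || anyDuplicated(metal) ||
        any(metal < 1L) || any(metal > n)) {
      stop("'metal' must be 4 distinct ligand residue indices within 1..", n)
    }
  }
  structure(list(segments = data.frame(kind = kinds, length = lens,
                                       stringsAsFactors = FALSE),
                 n_residues = n, metal = metal, seed = as.integer(seed)),
            class = "chain_spec")
}

#' @export
print.chain_spec <- function(x, ...) {
  cat(sprintf("Chain spec: %d residues [%s]%s, seed %d\n", x$n_residues,
              paste(sprintf("%s(%d)", x$segments$kind, x$segments$length),
                    collapse = " + "),
              if (is.null(x$metal)) "" else
                paste0(", metal on (", paste(x$metal, collapse = ", "), ")"),
              x$seed))
  invisible(x)
}

# geometry constants (Angstrom / degrees): virtual C-alpha bond, ideal
# alpha-helix (rise, twist, radius), hairpin strand separation. Chosen to give
# realistic coarse-grained contact densities at the 7.3 A GNM cutoff.
CA_STEP <- 3.8
HELIX_RISE <- 1.5
HELIX_TURN <- 100 * pi / 180
HELIX_RADIUS <- 2.3
HAIRPIN_SEP <- 5.0
METAL_MAX_DIST <- 7.3

#' Build coordinates for a synthetic chain
#'
#' Generates a C-alpha trace with ~3.8 Angstrom consecutive spacing. Loop
#' segments walk with a gentle deterministic 3D wobble (exact 3.8 A steps);
#' strands are straight; hairpins walk a flat "U" whose strands lie 5 A
#' apart; helices use ideal alpha-helix C-alpha geometry (rise 1.5 A, 100
#' degree twist, radius 2.3 A). A helix that is not the first segment is
#' folded back over the previously built body (offset upward), which is what
#' makes four-ligand metal sites geometrically feasible. If a metal is
#' requested, the pseudo-metal node is placed at the centroid of the four
#' ligand C-alphas; any ligand-metal distance at or above 7.3 A is an error
#' (infeasible site).
#'
#' @param spec a [chain_spec()].
#' @param jitter_sd optional Gaussian jitter (Angstrom, sd per coordinate)
#'   applied to the protein trace before metal placement, seeded from
#'   `spec$seed`.
#' @return A [cg_structure()] with the metal node (if any) appended last.
#' @examples
#' make_chain(chain_spec(c(loop = 3)))
#' toy_zinc_finger()
#' @export
make_chain <- function(spec, jitter_sd = 0) {
  stopifnot(inherits(spec, "chain_spec"))
  pts <- NULL
  dir <- c(1, 0, 0)
  for (si in seq_len(nrow(spec$segments))) {
    kind <- spec$segments$kind[si]
    len <- spec$segments$length[si]
    first <- is.null(pts)
    if (kind == "helix") {
      if (first) {
        p0 <- c(0, 0, 0)
        axis <- dir
      } else {
        cen <- colMeans(pts)
        h <- c(cen[1:2] - pts[nrow(pts), 1:2], 0)
        h <- if (sqrt(sum(h^2)) < 1e-9) c(-dir[1:2], 0) else h
        axis <- unit3(h)
        join <- unit3(2.05 * axis + c(0, 0, 3.2))
        p0 <- pts[nrow(pts), ] + CA_STEP * join
      }
      seg <- seg_helix(len, p0, axis)
    } else {
      p0 <- if (first) c(0, 0, 0) else pts[nrow(pts), ] + CA_STEP * dir
      seg <- switch(kind,
        loop = seg_loop(len, p0, dir),
        strand = seg_strand(len, p0, dir),
        hairpin = seg_hairpin(len, p0, dir)
      )
    }
    pts <- rbind(pts, seg$points)
    dir <- seg$end_dir
  }
  if (jitter_sd > 0) {
    pts <- with_seed(spec$seed,
                     pts + matrix(rnorm(length(pts), 0, jitter_sd), nrow(pts)))
  }

  n <- nrow(pts)
  labels <- data.frame(chain = "A", resno = seq_len(n), resname = "GLY",
                       insert = "", stringsAsFactors = FALSE)
  is_metal <- rep(FALSE, n)
  if (!is.null(spec$metal)) {
    lig <- pts[spec$metal, , drop = FALSE]
    m <- colMeans(lig)
    dmax <- sqrt(max(rowSums((lig - matrix(m, 4, 3, byrow = TRUE))^2)))
    if (dmax >= METAL_MAX_DIST) {
      stop(sprintf(paste0("infeasible metal placement: ligand-metal distance ",
                          "%.2f A >= %.1f A"), dmax, METAL_MAX_DIST))
    }
    pts <- rbind(pts, m)
    labels <- rbind(labels, data.frame(chain = "A", resno = n + 1L,
                                       resname = "ZN", insert = "",
                                       stringsAsFactors = FALSE))
    is_metal <- c(is_metal, TRUE)
  }
  cg_structure(labels, pts, is_metal, model = 1L)
}

#' Canonical synthetic zinc-finger fixture
#'
#' A 31-residue beta-hairpin + alpha-helix + C-terminal loop architecture
#' with a pseudo-metal node bound to residues 5, 10, 23 and 27 (mimicking the
#' Cys2His2 ligand layout of a classical zinc finger: two ligands on the
#' hairpin, one on the helix, one on the C-terminal loop), for 32 nodes in
#' total with the metal as node 32. Set `metal = FALSE` for the apo form.
#'
#' @param seed seed stored in the spec (the default build is deterministic).
#' @param metal include the pseudo-metal node?
#' @param jitter_sd optional coordinate jitter passed to [make_chain()].
#' @return A [cg_structure()].
#' @export
toy_zinc_finger <- function(seed = 1L, metal = TRUE, jitter_sd = 0) {
  spec <- chain_spec(c(hairpin = 12, loop = 2, helix = 12, loop = 5),
                     metal = if (metal) c(5L, 10L, 23L, 27L) else NULL,
                     seed = seed)
  make_chain(spec, jitter_sd = jitter_sd)
}

#' Simulate experimental B-factors from a known GNM
#'
#' Generates per-protein-node observations
#' `B_i = 8*pi^2 * kt_over_gamma * [Gamma^+]_ii + eps_i` with Gaussian noise
#' `eps_i ~ N(0, noise_sd)` truncated at zero, where the Kirchhoff matrix is
#' built at the 7.3 A cutoff. With `noise_sd = 0` the values equal the GNM
#' prediction exactly, so [fit_scale()] recovers `kt_over_gamma` to machine
#' precision — the basis of the scale-recovery tests.
#'
#' @param structure a [cg_structure()] whose network is connected at 7.3 A.
#' @param kt_over_gamma true fluctuation scale (Angstrom^2), > 0.
#' @param noise_sd standard deviation of the additive noise (Angstrom^2).
#' @param seed integer seed for the noise.
#' @param cutoff contact cutoff used to build the generating network.
#' @return An `experimental_bfactors` object with `source = "simulated"`.
#' @export
simulate_bfactors <- function(structure, kt_over_gamma, noise_sd = 0,
                              seed = 1L, cutoff = 7.3) {
  stopifnot(kt_over_gamma > 0, noise_sd >= 0)
  topo <- build_topology(structure, cutoff)
  sp <- decompose_modes(kirchhoff_matrix(topo), kind = "gnm")
  if (sp$n_zero > 1L) {
    stop("the contact network is disconnected at cutoff ", cutoff,
         " A (", sp$n_zero, " components); cannot simulate B-factors")
  }
  shape <- diag(pseudo_inverse(sp))[!structure$is_metal]
  b <- 8 * pi^2 * kt_over_gamma * shape
  if (noise_sd > 0) {
    b <- b + with_seed(seed, rnorm(length(b), 0, noise_sd))
  }
  new_experimental_bfactors(pmax(b, 0), "simulated")
}

# ---- segment builders ------------------------------------------------------

seg_loop <- function(n, p0, dir) {
  pts <- matrix(NA_real_, n, 3)
  pts[1, ] <- p0
  d <- unit3(dir)
  a1 <- perp_axis(d)
  for (k in seq_len(n - 1)) {
    a2 <- unit3(cross3(d, a1))
    ax <- if (k %% 2L == 1L) a1 else a2
    d <- rotate3(d, ax, -0.35)
    pts[k + 1, ] <- pts[k, ] + CA_STEP * d
  }
  list(points = pts, end_dir = d)
}

seg_strand <- function(n, p0, dir) {
  d <- unit3(dir)
  k <- seq_len(n) - 1
  list(points = sweep(outer(k * CA_STEP, d), 2, p0, "+"), end_dir = d)
}

seg_helix <- function(n, p0, axis) {
  a <- unit3(axis)
  zhat <- c(0, 0, 1)
  e1 <- -zhat + sum(zhat * a) * a
  e1 <- if (sqrt(sum(e1^2)) < 1e-9) c(1, 0, 0) else unit3(e1)
  e2 <- unit3(cross3(a, e1))
  c0 <- p0 - HELIX_RADIUS * e1
  k <- seq_len(n) - 1
  theta <- k * HELIX_TURN
  pts <- matrix(rep(c0, each = n), n, 3) +
    HELIX_RADIUS * (outer(cos(theta), e1) + outer(sin(theta), e2)) +
    outer(k * HELIX_RISE, a)
  list(points = pts, end_dir = a)
}

# flat "U": straight strand, semicircular turn of radius HAIRPIN_SEP/2,
# straight return strand; residues placed at exact 3.8 A chords along the path
seg_hairpin <- function(n, p0, dir) {
  u <- unit3(dir)
  v <- perp_axis(u)               # in-plane normal toward the return strand
  rho <- HAIRPIN_SEP / 2
  L1 <- CA_STEP * max(floor((n - 2) / 2), 1)
  path_point <- function(t) {
    if (t <= L1) return(p0 + t * u)
    s <- t - L1
    arc <- pi * rho
    Cc <- p0 + L1 * u + rho * v
    if (s <= arc) {
      phi <- s / rho
      return(Cc - rho * cos(phi) * v + rho * sin(phi) * u)
    }
    Cc + rho * v - (s - arc) * u
  }
  pts <- matrix(NA_real_, n, 3)
  pts[1, ] <- p0
  t_cur <- 0
  for (k in seq_len(n - 1)) {
    f <- function(t) sqrt(sum((path_point(t) - pts[k, ])^2)) - CA_STEP
    t_hi <- t_cur + CA_STEP + 0.1
    while (f(t_hi) < 0) t_hi <- t_hi + 0.5
    t_cur <- stats::uniroot(f, c(t_cur + 1e-9, t_hi), tol = 1e-12)$root
    pts[k + 1, ] <- path_point(t_cur)
  }
  list(points = pts, end_dir = unit3(pts[n, ] - pts[n - 1, ]))
}

# a deterministic unit vector perpendicular to d
perp_axis <- function(d) {
  cand <- cross3(c(0, 0, 1), d)
  if (sqrt(sum(cand^2)) < 1e-9) cand <- cross3(c(0, 1, 0), d)
  unit3(cand)
}
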