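test_that("contact classification follows the distance cutoff and chain rule", {
  # two consecutive nodes 5 A apart: covalent
  s2 <- straight_chain(2, step = 5.0)
  t2 <- build_topology(s2, 7.3)
  expect_equal(nrow(t2$covalent), 1)
  expect_equal(nrow(t2$noncovalent), 0)

  # nonconsecutive nodes 8 A apart: no contact at 7.3
  s3 <- straight_chain(3, step = 4.0)  # d13 = 8
  t3 <- build_topology(s3, 7.3)
  expect_false("1-3" %in% enmfold:::pair_key(t3$noncovalent))

  # straight 5-node chain at 3.8 A spacing: only the 4 consecutive pairs
  # (next-nearest distance 7.6 exceeds the cutoff)
  s5 <- straight_chain(5)
  t5 <- build_topology(s5, 7.3)
  expect_equal(nrow(t5$covalent), 4)
  expect_equal(nrow(t5$noncovalent), 0)

  # covalent springs survive even beyond the cutoff
  s_far <- straight_chain(2, step = 9.0)
  t_far <- build_topology(s_far, 7.3)
  expect_equal(nrow(t_far$covalent), 1)

  # metal-residue bonds are noncovalent
  tz <- build_topology(toy_zinc_finger(), 7.3)
  zn_pairs <- tz$noncovalent[tz$noncovalent[, 2] == 32, , drop = FALSE]
  expect_gte(nrow(zn_pairs), 4)
  expect_false(any(tz$covalent == 32))
})

test_that("the Kirchhoff matrix has -1 contacts, degree diagonal, zero row sums", {
  K <- kirchhoff_matrix(path3_topology())
  expect_equal(diag(K), c(1, 2, 1))
  expect_equal(K[1, 2], -1)
  expect_equal(K[1, 3], 0)

  tri <- new_topo(3, rbind(c(1, 2), c(2, 3)), rbind(c(1, 3)))
  Kt <- kirchhoff_matrix(tri)
  expect_equal(diag(Kt), c(2, 2, 2))
  expect_true(all(Kt[upper.tri(Kt)] == -1))

  s <- toy_zinc_finger()
  Ks <- kirchhoff_matrix(build_topology(s, 7.3))
  expect_equal(Ks, oracle_kirchhoff_structure(s, 7.3))
  expect_equal(rowSums(Ks), rep(0, 32))
})

test_that("path-3 decomposition matches the closed form", {
  sp <- path3_spectrum()
  expect_equal(sp$values, c(0, 1, 3), tolerance = 1e-10)
  expect_equal(sp$n_zero, 1)
  expect_equal(pseudo_inverse(sp), path3_pinv_exact, tolerance = 1e-10)
})

test_that("the spectral pseudo-inverse is a Moore-Penrose inverse", {
  for (seed in 1:5) {
    tp <- random_topology(12, seed)
    K <- kirchhoff_matrix(new_topo(tp$n, tp$covalent, tp$noncovalent))
    G <- pseudo_inverse(decompose_modes(K))
    expect_lt(max(abs(K %*% G %*% K - K)), 1e-8)
    expect_lt(max(abs(G %*% K %*% G - G)), 1e-8)
    expect_equal(G, t(G), tolerance = 1e-10)
  }
})

test_that("zero-mode count equals the number of connected components", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(6:15, 1)
    # random graph, possibly disconnected
    K <- matrix(0, n, n)
    pairs <- which(upper.tri(K), arr.ind = TRUE)
    on <- runif(nrow(pairs)) < 0.12
    K[pairs[on, , drop = FALSE]] <- -1
    K <- K + t(K)
    diag(K) <- -rowSums(K)
    sp <- decompose_modes(K)
    expect_equal(sp$n_zero, oracle_components(K))
  }
})

test_that("mean-square fluctuations and B-factors follow the GNM closed forms", {
  sp <- path3_spectrum()
  expect_equal(mean_square_fluctuations(sp, 1), c(5, 2, 5) / 3,
               tolerance = 1e-10)
  expect_equal(mean_square_fluctuations(sp, 0), rep(0, 3))
  expect_equal(predicted_bfactors(mean_square_fluctuations(sp, 1)),
               (8 * pi^2 / 3) * c(5, 2, 5) / 3, tolerance = 1e-10)
  expect_equal(predicted_bfactors(rep(3 / (8 * pi^2), 4)), rep(1, 4))
  # palindromic topology gives a palindromic profile
  msf <- mean_square_fluctuations(sp, 1)
  expect_equal(msf, rev(msf))
})

test_that("fit_scale recovers a noiseless scale and is scale-free in r", {
  shape <- c(5, 2, 5, 3, 7) / 9
  fit <- fit_scale(shape, 8 * pi^2 * 0.05 * shape)
  expect_equal(fit$kt_over_gamma, 0.05, tolerance = 1e-12)
  expect_equal(fit$correlation, 1.0, tolerance = 1e-12)

  set.seed(42)
  b <- runif(5, 1, 10)
  f1 <- fit_scale(shape, b)
  f2 <- fit_scale(shape, 3.7 * b)
  expect_equal(f1$correlation, f2$correlation, tolerance = 1e-12)
  expect_equal(f2$kt_over_gamma, 3.7 * f1$kt_over_gamma, tolerance = 1e-12)

  expect_error(fit_scale(shape, rep(2, 5)), "zero variance")
  expect_error(fit_scale(shape, c(1, 2)), "differ in length")
})

test_that("uncorrelated experimental vectors give low B-factor correlation", {
  g <- gnm(toy_zinc_finger(), 7.3)
  shape <- g$shape[1:31]
  cors <- vapply(1:100, function(seed) {
    set.seed(seed)
    abs(fit_scale(shape, runif(31, 5, 50))$correlation)
  }, numeric(1))
  expect_lt(mean(cors), 0.35)
})

test_that("cross-correlations are normalized with the path-3 closed form", {
  sp <- path3_spectrum()
  C <- cross_correlation_map(sp)
  expect_equal(C[1, 3], -0.8, tolerance = 1e-10)
  expect_equal(diag(C), rep(1, 3))
  g <- gnm(toy_zinc_finger())
  Cg <- cross_correlation_map(g)
  expect_true(all(abs(Cg) <= 1 + 1e-8))
  expect_equal(diag(Cg), rep(1, 32))
  expect_equal(Cg, t(Cg), tolerance = 1e-10)
})

test_that("disconnected components are uncorrelated", {
  # two separate edges: 1-2 and 3-4
  K <- kirchhoff_matrix(new_topo(4, rbind(c(1, 2), c(3, 4)), NULL))
  sp <- decompose_modes(K)
  expect_equal(sp$n_zero, 2)
  C <- cross_correlation_map(sp)
  expect_equal(C[1:2, 3:4], matrix(0, 2, 2))
  expect_equal(C[1, 2], -1, tolerance = 1e-10)
})

test_that("mode-shape profiles are normalized squared eigenvector averages", {
  sp <- path3_spectrum()
  expect_equal(mode_shape_profile(sp, "slowest", 1), c(0.5, 0, 0.5),
               tolerance = 1e-10)
  g <- gnm(toy_zinc_finger())
  for (k in c(1, 3, 5)) {
    expect_equal(sum(mode_shape_profile(g, "slowest", k)), 1, tolerance = 1e-10)
    expect_equal(sum(mode_shape_profile(g, "fastest", k)), 1, tolerance = 1e-10)
  }
  expect_error(mode_shape_profile(sp, "slowest", 5), "nonzero modes")
  # slowest-all with inverse-eigenvalue weighting recovers the MSF shape
  nz <- length(g$spectrum$values) - g$spectrum$n_zero
  w <- mode_shape_profile(g, "slowest", nz, weighted = TRUE)
  expect_equal(w / sum(w), g$shape / sum(g$shape), tolerance = 1e-10)
})

test_that("fast modes peak at the metal site and tightly packed ligands", {
  # the pseudo-metal has the highest coordination in the fixture, and the
  # hairpin/helix ligands (or their immediate sequence neighbours, where the
  # local packing peak sits) rank in the top third of the fastest-5 profile;
  # the C-terminal-loop ligand is intentionally excluded: a floppy terminal
  # loop does not produce a fast-mode peak
  g <- gnm(toy_zinc_finger())
  pf <- mode_shape_profile(g, "fastest", 5)
  rk <- rank(-pf)
  expect_lte(rk[32], 3)
  for (lig in c(5, 10, 23)) {
    expect_lte(min(rk[(lig - 1):(lig + 1)]), ceiling(32 / 3))
  }
})

test_that("distance fluctuations follow the pseudo-inverse closed forms", {
  # single spring between two nodes
  sp2 <- decompose_modes(kirchhoff_matrix(new_topo(2, rbind(c(1, 2)), NULL)))
  expect_equal(pseudo_inverse(sp2),
               matrix(c(1, -1, -1, 1), 2, 2) / 4, tolerance = 1e-10)
  expect_equal(distance_fluctuation(sp2, 1, 2, 1), 3, tolerance = 1e-10)

  sp <- path3_spectrum()
  expect_equal(distance_fluctuation(sp, 1, 2, 1), 3, tolerance = 1e-10)
  expect_equal(distance_fluctuation(sp, 1, 3, 1), 6, tolerance = 1e-10)
  expect_equal(distance_fluctuation(sp, 2, 1, 1),
               distance_fluctuation(sp, 1, 2, 1))
  expect_equal(distance_fluctuation(sp, 2, 2, 1), 0, tolerance = 1e-12)
  # the scale multiplies uniformly
  expect_equal(distance_fluctuation(sp, 1, 3, 0.068), 0.068 * 6,
               tolerance = 1e-10)
})

test_that("scale recovery from noisy simulated B-factors is unbiased", {
  s <- toy_zinc_finger()
  g <- gnm(s, 7.3)
  shape <- g$shape[1:31]
  signal_sd <- sd(8 * pi^2 * 0.068 * shape)
  est <- vapply(1:50, function(seed) {
    b <- simulate_bfactors(s, 0.068, noise_sd = 0.1 * signal_sd, seed = seed)
    fit_scale(shape, b)$kt_over_gamma
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.068) / 0.068, 0.05)
})

test_that("GNM fluctuations agree with an independent implementation", {
  # metal-free toy against bio3d's Gaussian network model at the same cutoff
  s <- make_chain(chain_spec(c(hairpin = 10, loop = 2, helix = 10)))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(s, f)
  pdb <- bio3d::read.pdb(f)
  ref <- bio3d::gnm(pdb, cutoff = 7.3)
  msf <- mean_square_fluctuations(gnm(s, 7.3), 1)
  expect_gt(cor(msf, ref$fluctuations), 0.9999)
})

test_that("gnm objects expose the usual modelling accessors", {
  s <- toy_zinc_finger()
  b <- simulate_bfactors(s, 0.068, noise_sd = 0.3, seed = 5)
  g <- gnm(s, bfactors = b)
  expect_s3_class(g, "gnm")
  expect_named(coef(g), "kt_over_gamma")
  expect_length(fitted(g), 31)
  expect_equal(residuals(g), b$values - fitted(g))
  expect_output(print(g), "kT/gamma")
  expect_output(print(summary(g)), "zero modes")
  expect_error(fitted(gnm(s)), "nothing was fitted")
})
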