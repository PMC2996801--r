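# a triangle with covalent backbone 1-2, 2-3 and one noncovalent contact 1-3,
# realized geometrically so unfold() can build it from coordinates
triangle_structure <- function() {
  cg_structure(data.frame(chain = "A", resno = 1:3, resname = "GLY",
                          insert = ""),
               rbind(c(0, 0, 0), c(3.8, 0, 0), c(1.9, 3.3, 0)),
               rep(FALSE, 3))
}

test_that("a single noncovalent contact gives a single break event", {
  s <- triangle_structure()
  tr <- unfold(s, cutoff = 7.3)
  expect_equal(nrow(tr$events), 1)
  expect_equal(unlist(tr$events[1, c("i", "j")]), c(i = 1, j = 3))
  expect_equal(tr$events$lnnc, 1)
  final <- snapshot_topology(tr, 1)
  expect_equal(nrow(final$noncovalent), 0)
  expect_equal(nrow(final$covalent), 2)
})

test_that("logged fluctuations equal the recomputed value at break time", {
  s <- triangle_structure()
  tr <- unfold(s, cutoff = 7.3, kt_over_gamma = 1)
  # triangle Kirchhoff pseudo-inverse: distance fluctuation of (1,3) = 2
  expect_equal(tr$events$fluctuation[1], 2, tolerance = 1e-10)

  toy <- toy_zinc_finger()
  trt <- unfold(toy, cutoff = 7.3)
  for (step in c(1, 10, 50)) {
    topo <- snapshot_topology(trt, step - 1)
    sp <- decompose_modes(kirchhoff_matrix(topo))
    f <- distance_fluctuation(sp, trt$events$i[step], trt$events$j[step], 1)
    expect_equal(trt$events$fluctuation[step], f, tolerance = 1e-10)
  }
})

test_that("the full toy trajectory matches a from-scratch brute-force oracle", {
  s <- toy_zinc_finger()
  tr <- unfold(s, cutoff = 7.3)
  orc <- oracle_unfold(s, cutoff = 7.3)
  expect_equal(nrow(tr$events), nrow(orc))
  expect_equal(tr$events$i, unname(orc[, "i"]))
  expect_equal(tr$events$j, unname(orc[, "j"]))
  expect_equal(tr$events$fluctuation, unname(orc[, "fluctuation"]),
               tolerance = 1e-8)
})

test_that("trajectory bookkeeping invariants hold", {
  s <- toy_zinc_finger()
  tr <- unfold(s, cutoff = 7.3)
  E <- nrow(tr$initial$noncovalent)
  expect_equal(tr$events$step, seq_len(E))
  expect_equal(tr$events$lnnc, seq_len(E))          # LNNC increments by 1
  expect_equal(tr$events$remaining, E - seq_len(E))
  # each noncovalent pair breaks exactly once, covalent pairs never
  ev_keys <- enmfold:::pair_key(as.matrix(tr$events[, c("i", "j")]))
  expect_setequal(ev_keys, enmfold:::pair_key(tr$initial$noncovalent))
  expect_false(any(ev_keys %in% enmfold:::pair_key(tr$initial$covalent)))
  # determinism
  tr2 <- unfold(s, cutoff = 7.3)
  expect_identical(tr$events, tr2$events)
})

test_that("snapshots reconstruct the topology at a given LNNC", {
  s <- toy_zinc_finger()
  tr <- unfold(s, cutoff = 7.3)
  E <- nrow(tr$events)
  t0 <- snapshot_topology(tr, 0)
  expect_identical(t0$noncovalent, tr$initial$noncovalent)
  tE <- snapshot_topology(tr, E)
  expect_equal(nrow(tE$noncovalent), 0)
  t20 <- snapshot_topology(tr, 20)
  expect_equal(nrow(t20$noncovalent), nrow(tr$initial$noncovalent) - 20)
  expect_error(snapshot_topology(tr, E + 1), "between 0 and")
})

test_that("contact maps and edge lists stay mutually consistent", {
  s <- toy_zinc_finger()
  tr <- unfold(s, cutoff = 7.3)
  n_init <- nrow(tr$initial$covalent) + nrow(tr$initial$noncovalent)
  for (k in c(0, 20, 47)) {
    topo <- snapshot_topology(tr, k)
    M <- contact_map(topo)
    expect_true(isSymmetric(M))
    expect_equal(sum(M) / 2, n_init - k)
    E <- contact_edges(topo)
    M2 <- matrix(FALSE, topo$n_nodes, topo$n_nodes)
    M2[cbind(E$i, E$j)] <- TRUE
    M2[cbind(E$j, E$i)] <- TRUE
    expect_identical(M, M2)
  }
})

test_that("bond break order reports steps and rejects covalent queries", {
  s <- triangle_structure()
  tr <- unfold(s)
  bo <- bond_break_order(tr, rbind(c(1, 3)))
  expect_equal(bo$step, 1)
  expect_error(bond_break_order(tr, rbind(c(1, 2))), "covalent")
  expect_error(bond_break_order(tr, rbind(c(1, 30))), "not among")

  toy <- toy_zinc_finger()
  trt <- unfold(toy)
  zn <- cbind(c(5, 10, 23, 27), 32)
  bo_t <- bond_break_order(trt, zn)
  orc <- oracle_unfold(toy, 7.3)
  orc_steps <- vapply(seq_len(4), function(r) {
    which(orc[, "i"] == zn[r, 1] & orc[, "j"] == zn[r, 2])
  }, integer(1))
  expect_equal(bo_t$step, sort(orc_steps))
  expect_false(is.unsorted(bo_t$step))
})

test_that("snapshot cross-correlations stay valid along the trajectory", {
  s <- toy_zinc_finger()
  tr <- unfold(s, cutoff = 7.3)
  g <- gnm(s, cutoff = 7.3)
  expect_equal(snapshot_cross_correlation(tr, 0), cross_correlation_map(g),
               tolerance = 1e-10)
  for (k in c(20, 60, nrow(tr$events))) {
    C <- snapshot_cross_correlation(tr, k)
    expect_equal(diag(C), rep(1, 32))
    expect_true(all(abs(C) <= 1 + 1e-8))
    expect_equal(C, t(C), tolerance = 1e-10)
  }
  # once the metal is fully detached it is uncorrelated with the chain
  zn_steps <- bond_break_order(tr, cbind(which(
    contact_map(tr$initial)[, 32]), 32))$step
  C_end <- snapshot_cross_correlation(tr, max(zn_steps))
  expect_equal(C_end[32, -32], rep(0, 31))
  expect_equal(C_end[32, 32], 1)
})
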