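tab <- default_interaction_table()

test_that("charge variants substitute Q positions only", {
  v6 <- make_charge_variant(6, "+")
  expect_equal(sequence_string(v6), "KQKFKWKFKQK")
  expect_equal(net_charge(v6), 6L)
  v6m <- make_charge_variant(6, "-")
  expect_equal(sequence_string(v6m), "EQEFEWEFEQE")
  expect_equal(net_charge(v6m), -6L)
  v4 <- make_charge_variant(4, "-")
  expect_equal(net_charge(v4), -4L)

  v0 <- make_charge_variant(0, "+", positions = integer(0))
  expect_equal(sequence_string(v0), sequence_string(qf_scaffold()))
  expect_equal(net_charge(v0), 0L)

  expect_error(make_charge_variant(1, "+", positions = 4), "hydrophobic core")
  expect_error(make_charge_variant(1, "+", positions = 99), "out of range")
  expect_error(make_charge_variant(3, "+", positions = c(1, 3)), "must equal")
})

test_that("ideal sheets carry their ground truth", {
  # 6-strand alternating sheet: a single fibril with perfect alternation
  sh <- make_ideal_sheet("+-+-+-")
  g <- build_association_graph(sh$snapshot, sh$topology, tab)
  cl <- classify_clusters(g)
  expect_length(cl$fibrils, 1)
  expect_length(cl$fibrils[[1]], 6)
  expect_length(cl$free, 0)
  s <- strand_order_stats(cl$fibrils[[1]], g)
  expect_equal(s$n_alternating_neighbors, 5)
  expect_equal(s$n_like_charge_neighbors, 0)
  expect_equal(s$cation_fraction, 0.5)

  # 2-strand sheet: one oligomer
  sh2 <- make_ideal_sheet("+-")
  cl2 <- classify_clusters(
    build_association_graph(sh2$snapshot, sh2$topology, tab))
  expect_length(cl2$oligomers, 1)
  expect_length(cl2$fibrils, 0)

  # 5 versus 6 strands: oligomer versus fibril boundary
  cl5 <- classify_clusters(build_association_graph(
    make_ideal_sheet("+-+-+")$snapshot,
    make_ideal_sheet("+-+-+")$topology, tab))
  expect_length(cl5$oligomers, 1)
  expect_length(cl5$fibrils, 0)
})

test_that("a bilayer joins its leaflets through hydrophobic contacts", {
  bl <- make_ideal_sheet("+-+-", bilayer = TRUE)
  expect_equal(bl$ground_truth$n_strands, 8)
  g <- build_association_graph(bl$snapshot, bl$topology, tab)
  cl <- classify_clusters(g)
  expect_length(cl$fibrils, 1)
  expect_length(cl$fibrils[[1]], 8)
  # cross-leaflet edges exist and are hydrophobic-only joins
  cross <- g$edges[(g$edges$i <= 4) != (g$edges$j <= 4) & g$edges$joined, ]
  expect_gt(nrow(cross), 0)
  expect_true(all(cross$n_hydrophobic_contacts >= 1))
})

test_that("sheet fixtures satisfy the engine's state invariants", {
  for (pattern in c("+-", "+-+-+-")) {
    sh <- make_ideal_sheet(pattern)
    st <- structure(
      list(positions = sh$snapshot$positions,
           velocities = matrix(0, nrow(sh$snapshot$positions), 3),
           box_side = sh$snapshot$box_side, T_star = 0.2, time = 0,
           collision_count = 0,
           hb_partner = rep(NA_integer_, nrow(sh$snapshot$positions)),
           topology = sh$topology, table = tab, seed = 1),
      class = "dmd_state")
    tr <- run_dmd(st, 0, ghost_rate = 0)
    expect_gt(min(tr$audit$min_core_gap), -1e-9)   # no core overlap
    b <- sh$topology$bonds
    bl <- sqrt(rowSums((sh$snapshot$positions[b$i, ] -
                        sh$snapshot$positions[b$j, ])^2))
    expect_true(all(bl >= b$min - 1e-9 & bl <= b$max + 1e-9))
  }
})

test_that("kinetics toy respects its schedule and boundaries", {
  peps <- rep(list(make_charge_variant(4, "+")), 10)
  # 10 peptides pairing into 5 dimers
  sched <- data.frame(time = 1:5, a = c(1, 3, 5, 7, 9), b = c(2, 4, 6, 8, 10))
  toy <- make_kinetics_toy(sched, peps)
  last <- toy$expected[nrow(toy$expected), ]
  expect_equal(unname(last["n_free"]), 0)
  expect_equal(unname(last["n_in_oligomers"]), 10)
  expect_equal(unname(last["n_in_fibrils"]), 0)

  # staged growth 1 -> 8: the fibril class appears when size exceeds 5
  sched2 <- data.frame(time = 1:7, a = rep(1, 7), b = 2:8)
  toy2 <- make_kinetics_toy(sched2, rep(list(make_charge_variant(6, "-")), 8))
  kin2 <- kinetics_series(toy2)
  expect_equal(kin2$n_in_fibrils, c(0, 0, 0, 0, 0, 6, 7, 8))

  # inconsistent schedule: merging a cluster with itself
  expect_error(
    make_kinetics_toy(data.frame(time = c(1, 2), a = c(1, 1), b = c(2, 2)),
                      peps),
    "merges a cluster with itself")
})

test_that("generators are deterministic under a fixed seed", {
  sp <- catch_sequences()
  species <- list(list(peptide = sp[["CATCH_like(2+)"]], count = 3))
  s1 <- init_system(species, 90, 0.2, seed = 21)
  s2 <- init_system(species, 90, 0.2, seed = 21)
  expect_identical(s1$positions, s2$positions)
  sh1 <- make_ideal_sheet("+-+")
  sh2 <- make_ideal_sheet("+-+")
  expect_identical(sh1$snapshot$positions, sh2$snapshot$positions)
})
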