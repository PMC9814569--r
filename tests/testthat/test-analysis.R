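tab <- default_interaction_table()

test_that("hydrogen-bond detection on constructed fixtures", {
  # idealized 2-strand sheet: every cross-strand NH/CO pair in registry
  sh <- make_ideal_sheet("+-")
  hb <- detect_hbonds(sh$snapshot, sh$topology, tab)
  inter <- hb[hb$chain_nh != hb$chain_co, ]
  expect_gte(nrow(inter), 8)
  # one bond per NH and per CO at most
  expect_false(any(duplicated(hb$nh)))
  expect_false(any(duplicated(hb$co)))

  # a single isolated extended peptide has no hydrogen bonds
  one <- dmdpep:::system_topology(list(parse_sequence("KQKFKWKFKQK")), tab)
  snap <- list(positions = one$templates[[1]] + 40, box_side = 120)
  expect_equal(nrow(detect_hbonds(snap, one, tab)), 0)

  # well-separated dilute peptides: no bonds, all free
  sp <- catch_sequences()
  st <- init_system(list(list(peptide = sp[["CATCH_like(6+)"]], count = 4)),
                    box_side = 300, T_star = 0.2, seed = 9)
  snap <- list(positions = st$positions, box_side = 300)
  expect_equal(nrow(detect_hbonds(snap, st$topology, tab)), 0)
  g <- build_association_graph(snap, st$topology, tab)
  cl <- classify_clusters(g)
  expect_length(cl$free, 4)
})

test_that("detection is invariant under global rotation and translation", {
  sh <- make_ideal_sheet("+-+")
  hb0 <- detect_hbonds(sh$snapshot, sh$topology, tab)
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  pos <- sh$snapshot$positions %*% R
  pos <- sweep(pos, 2, c(11, -3, 7), "+")
  # rotate into a large box to keep everything inside
  snap <- list(positions = pos %% 500, box_side = 500)
  sh2 <- list(positions = pos, box_side = 500)
  hb1 <- detect_hbonds(sh2, sh$topology, tab)
  expect_equal(nrow(hb1), nrow(hb0))
  expect_equal(hb1$nh, hb0$nh)
  expect_equal(hb1$co, hb0$co)
  expect_equal(hb1$distance, hb0$distance, tolerance = 1e-9)
})

test_that("H-bond count shrinks monotonically with the capture distance", {
  sh <- make_ideal_sheet("+-+-")
  counts <- vapply(c(5.0, 4.6, 4.2, 3.8), function(d) {
    t2 <- tab
    t2$hb$distance <- d
    nrow(detect_hbonds(sh$snapshot, sh$topology, t2))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("the two-condition join rule builds the association graph", {
  sh <- make_ideal_sheet("+-")
  g <- build_association_graph(sh$snapshot, sh$topology, tab)
  e <- g$edges[g$edges$i == 1 & g$edges$j == 2, ]
  expect_gte(e$n_hbonds, 6)        # majority of 11 sites
  expect_true(e$joined)

  # raising the majority threshold above the bond count breaks the join
  # unless hydrophobic contacts remain
  g2 <- build_association_graph(sh$snapshot, sh$topology, tab,
                                hb_majority_threshold = 50)
  e2 <- g2$edges[g2$edges$i == 1 & g2$edges$j == 2, ]
  expect_equal(e2$joined, e2$n_hydrophobic_contacts >= 1)
})

test_that("cluster classification handles the 5/6 boundary", {
  g <- make_test_graph(24, data.frame(
    i = c(2, 4, 5, 6, 7, 9, 10, 11, 12, 13, 15:23),
    j = c(3, 5, 6, 7, 8, 10, 11, 12, 13, 14, 16:24)))
  # components: {1}, {2,3}, {4..8}, {9..14}, {15..24}
  cl <- classify_clusters(g)
  expect_equal(cl$free, 1L)
  expect_equal(sort(lengths(cl$oligomers)), c(2, 5))
  expect_equal(sort(lengths(cl$fibrils)), c(6, 10))
})

test_that("cluster partition equals the flood-fill oracle on random graphs", {
  set.seed(99)
  for (k in 1:200) {
    n <- sample(2:20, 1)
    m <- sample(0:(2 * n), 1)
    edges <- if (m == 0) data.frame(i = integer(0), j = integer(0)) else {
      ij <- t(replicate(m, sample(n, 2)))
      data.frame(i = pmin(ij[, 1], ij[, 2]), j = pmax(ij[, 1], ij[, 2]))
    }
    g <- make_test_graph(n, edges)
    cl <- classify_clusters(g)
    want <- flood_fill_membership(n, edges)
    expect_equal(canonical_partition(cl$membership),
                 canonical_partition(want))
    # relabeling invariance: permute node ids
    perm <- sample(n)
    edges2 <- if (nrow(edges) == 0) edges else
      data.frame(i = pmin(perm[edges$i], perm[edges$j]),
                 j = pmax(perm[edges$i], perm[edges$j]))
    cl2 <- classify_clusters(make_test_graph(n, edges2))
    expect_equal(sort(tabulate(cl2$membership)),
                 sort(tabulate(cl$membership)))
  }
})

test_that("kinetics series conserves the peptide partition", {
  sched <- data.frame(time = c(1, 2, 3, 4),
                      a = c(1, 3, 1, 5), b = c(2, 4, 3, 6))
  peps <- rep(list(make_charge_variant(6, "+"), make_charge_variant(6, "-")),
              4)
  toy <- make_kinetics_toy(sched, peps)
  kin <- kinetics_series(toy)
  expect_equal(kin$n_free + kin$n_in_oligomers + kin$n_in_fibrils,
               rep(8, nrow(kin)))
  expect_equal(kin$n_free, toy$expected[, "n_free"], ignore_attr = TRUE)
  expect_equal(kin$n_in_oligomers, toy$expected[, "n_in_oligomers"],
               ignore_attr = TRUE)
  # a constant trajectory gives a constant series
  toy0 <- make_kinetics_toy(data.frame(time = numeric(0), a = integer(0),
                                       b = integer(0))[0, ], peps)
  kin0 <- kinetics_series(toy0)
  expect_equal(kin0$n_free, rep(8, nrow(kin0)))
})

test_that("time to depletion reads the series correctly", {
  kin <- data.frame(time = 0:4, n_free = c(10, 8, 5, 5, 2),
                    n_in_oligomers = c(0, 2, 5, 5, 8),
                    n_in_fibrils = 0, n_hbonds = 0)
  expect_equal(time_to_depletion(kin, 0.5), 2)
  expect_equal(time_to_depletion(kin, 0.2), 4)
  expect_true(is.na(time_to_depletion(kin, 0.1)))
})

test_that("strand-order statistics match hand enumeration", {
  # +-+-+- : 5 alternating neighbours, no mismatches
  g <- make_test_graph(6, data.frame(i = 1:5, j = 2:6, n_hbonds = 8L),
                       charges = c(6L, -6L, 6L, -6L, 6L, -6L))
  s <- strand_order_stats(1:6, g)
  expect_equal(s$n_alternating_neighbors, 5)
  expect_equal(s$n_like_charge_neighbors, 0)
  expect_equal(s$cation_fraction, 0.5)

  # ++-- : neighbours (+,+), (+,-), (-,-): 1 alternating, 2 like-charge
  g2 <- make_test_graph(4, data.frame(i = 1:3, j = 2:4, n_hbonds = 8L),
                        charges = c(4L, 4L, -4L, -4L))
  s2 <- strand_order_stats(1:4, g2)
  expect_equal(s2$n_alternating_neighbors, 1)
  expect_equal(s2$n_like_charge_neighbors, 2)
  expect_equal(s2$cation_fraction, 0.5)

  # random chains versus direct enumeration
  set.seed(7)
  for (k in 1:50) {
    n <- sample(3:12, 1)
    q <- sample(c(-6L, 6L), n, replace = TRUE)
    nhb <- sample(c(2L, 8L), n - 1, replace = TRUE)
    g3 <- make_test_graph(n, data.frame(i = 1:(n - 1), j = 2:n,
                                        n_hbonds = nhb), charges = q)
    s3 <- strand_order_stats(seq_len(n), g3)
    nb <- which(nhb >= 6)
    expect_equal(s3$n_alternating_neighbors,
                 sum(q[nb] * q[nb + 1] < 0))
    expect_equal(s3$n_like_charge_neighbors,
                 sum(q[nb] * q[nb + 1] > 0))
    expect_equal(s3$cation_fraction, mean(q > 0))
  }
})
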