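tab <- default_interaction_table()

test_that("pair potential lookup is symmetric and class-correct", {
  ff <- lookup_pair_potential(tab, "R:F", "R:F")
  expect_equal(ff$kind, "square_well")
  expect_equal(ff$sign, "attractive")
  expect_gt(ff$well_edge, ff$hard_core)

  expect_equal(lookup_pair_potential(tab, "CA", "CA")$kind, "hard_sphere")

  ke <- lookup_pair_potential(tab, "R:K", "R:E")
  ek <- lookup_pair_potential(tab, "R:E", "R:K")
  expect_identical(ke, ek)
  expect_equal(ke$sign, "attractive")
  expect_equal(lookup_pair_potential(tab, "R:K", "R:K")$sign, "repulsive")
  expect_equal(lookup_pair_potential(tab, "R:E", "R:E")$sign, "repulsive")
  expect_equal(lookup_pair_potential(tab, "R:Q", "R:Q")$sign, "attractive")

  hb <- lookup_pair_potential(tab, "NH", "CO")
  expect_equal(hb$kind, "hbond")
  expect_equal(hb$well_edge, tab$hb$distance)

  # exhaustive argument-order symmetry over all bead labels
  labels <- c("NH", "CA", "CO", paste0("R:", residue_table()$code))
  set.seed(3)
  for (k in 1:40) {
    ab <- sample(labels, 2)
    expect_identical(lookup_pair_potential(tab, ab[1], ab[2]),
                     lookup_pair_potential(tab, ab[2], ab[1]))
  }
})

test_that("reduced temperature implements kB T / eps_HB", {
  expect_equal(reduced_temperature(300), 8.31446e-3 * 300 / 12.47,
               tolerance = 1e-12)
  expect_equal(reduced_temperature(300), 0.2000, tolerance = 1e-3)
  expect_error(reduced_temperature(0), "positive")
  expect_error(reduced_temperature(-10), "positive")
  for (T in c(77, 300, 342)) {
    expect_equal(kelvin_from_reduced(reduced_temperature(T)), T,
                 tolerance = 1e-12)
  }
})

test_that("interaction table text format round-trips and patches", {
  f <- tempfile(fileext = ".txt")
  write_interaction_table(tab, f)
  back <- read_interaction_table(f)
  expect_equal(back$sidechain_depth, tab$sidechain_depth)
  expect_equal(back$well_width_ratio, tab$well_width_ratio)

  # a partial file patches single entries
  writeLines(c("# patch", "F W 1.5 0.5"), f)
  patched <- read_interaction_table(f)
  expect_equal(patched$sidechain_depth["F", "W"], 0.5)
  expect_equal(patched$sidechain_depth["W", "F"], 0.5)
  expect_equal(patched$sidechain_depth["K", "E"], tab$sidechain_depth["K", "E"])
  expect_error(read_interaction_table(textConnection("F Z 1.5 0.1")))
})

test_that("topology has four beads per residue and the full pseudo-bond set", {
  p11 <- parse_sequence("EQEFEWEFEQE")
  top <- build_topology(p11, tab)
  expect_equal(nrow(top$beads), 44)
  expect_equal(table(top$beads$kind)[["R"]], 11)
  # connectivity: pseudo-bond graph spans all beads
  g <- igraph::graph_from_edgelist(as.matrix(top$bonds[, c("i", "j")]),
                                   directed = FALSE)
  expect_equal(igraph::components(g)$no, 1)
  expect_true(all(top$bonds$min < top$bonds$ideal,
                  top$bonds$ideal < top$bonds$max))

  p1 <- parse_sequence("QF")
  top2 <- build_topology(p1, tab)
  expect_equal(nrow(top2$beads), 8)
  # per residue: three sidechain-attachment bonds
  r_bead <- which(top2$beads$kind == "R")[1]
  expect_equal(sum(top2$bonds$i == r_bead | top2$bonds$j == r_bead), 3)

  expect_error(build_topology(p11, structure(list(hs_sidechain = c(A = 1)),
                                             class = "interaction_table")))
})

test_that("a 96-peptide system counts 4224 beads", {
  sp <- catch_sequences()
  topo <- dmdpep:::system_topology(
    rep(list(sp[["CATCH_like(6+)"]], sp[["CATCH_like(6-)"]]), 48), tab)
  expect_equal(nrow(topo$beads), 96 * 44)
  expect_equal(length(unique(topo$beads$chain)), 96)
})

test_that("the extended template satisfies cores and bond windows", {
  for (seq in c("EQEFEWEFEQE", "KQKFKWKFKQK", "QQKFQFQFEQQ")) {
    top <- build_topology(parse_sequence(seq), tab)
    xyz <- top$template
    d <- as.matrix(dist(xyz))
    # every pseudo-bond at its ideal length by construction
    bl <- sqrt(rowSums((xyz[top$bonds$i, ] - xyz[top$bonds$j, ])^2))
    expect_equal(bl, top$bonds$ideal, tolerance = 1e-12)
    # no non-bonded core overlap (0.75 sigma for adjacent residues)
    beads <- top$beads
    bonded <- paste(pmin(top$bonds$i, top$bonds$j),
                    pmax(top$bonds$i, top$bonds$j))
    n <- nrow(xyz)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (paste(i, j) %in% bonded) next
        sig <- (beads$diameter[i] + beads$diameter[j]) / 2
        if (abs(beads$residue_index[i] - beads$residue_index[j]) <= 1) {
          sig <- 0.75 * sig
        }
        expect_gt(d[i, j], sig * (1 - 1e-9))
      }
    }
  }
})
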