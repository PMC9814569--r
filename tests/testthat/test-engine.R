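tab <- default_interaction_table()

test_that("concentration matches the canonical box and scales correctly", {
  expect_equal(concentration(96, 200), 19.93, tolerance = 1e-3)
  expect_equal(round(concentration(96, 200)), 20)
  expect_equal(concentration(0, 100), 0)
  expect_equal(concentration(10, 100) / concentration(10, 200), 8)
  expect_equal(concentration(16, box_side_for_concentration(16, 20)), 20,
               tolerance = 1e-9)
})

test_that("initialization is deterministic and satisfies the invariants", {
  sp <- catch_sequences()
  species <- list(list(peptide = sp[["CATCH_like(4+)"]], count = 2),
                  list(peptide = sp[["CATCH_like(4-)"]], count = 2))
  s1 <- init_system(species, box_side = 80, T_star = 0.2, seed = 11)
  s2 <- init_system(species, box_side = 80, T_star = 0.2, seed = 11)
  expect_identical(s1$positions, s2$positions)
  expect_identical(s1$velocities, s2$velocities)
  s3 <- init_system(species, box_side = 80, T_star = 0.2, seed = 12)
  expect_false(identical(s1$positions, s3$positions))

  # momentum zeroed, kinetic temperature exact
  m <- s1$topology$beads$mass
  expect_equal(max(abs(colSums(s1$velocities * m))), 0, tolerance = 1e-9)
  expect_equal(kinetic_temperature(s1), 0.2, tolerance = 1e-12)

  # bond windows hold in the initial state (minimum image: wrapped chains)
  b <- s1$topology$bonds
  dd <- s1$positions[b$i, ] - s1$positions[b$j, ]
  dd <- dd - 80 * round(dd / 80)
  bl <- sqrt(rowSums(dd^2))
  expect_true(all(bl >= b$min - 1e-9 & bl <= b$max + 1e-9))

  # packing failure reports the achieved count
  expect_error(
    init_system(list(list(peptide = sp[["CATCH_like(4+)"]], count = 50)),
                box_side = 30, T_star = 0.2, seed = 1, max_retries = 20),
    "packing failed")
})

test_that("zero-collision run returns the input state as one snapshot", {
  st <- make_free_bead_state(5, 50, seed = 2)
  tr <- run_dmd(st, 0, ghost_rate = 0)
  expect_equal(length(tr$times), 1)
  expect_equal(tr$snapshots[[1]], st$positions %% 50, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(tr$collision_count, 0)
})

test_that("microcanonical dynamics conserves energy and momentum", {
  sp <- catch_sequences()
  st <- init_system(list(list(peptide = sp[["CATCH_like(6+)"]], count = 1),
                         list(peptide = sp[["CATCH_like(6-)"]], count = 1)),
                    box_side = 60, T_star = 0.2, seed = 7)
  tr <- run_dmd(st, 2e5, snapshot_every = 2e4, ghost_rate = 0)
  a <- tr$audit
  E <- a$KE + a$U
  expect_lt(max(abs(E - E[1])), 1e-8)                      # total drift
  expect_equal(a$U, a$U_exact, tolerance = 1e-10)          # audit bookkeeping
  expect_lt(max(abs(c(a$px, a$py, a$pz))), 1e-8)           # momentum
  expect_true(all(a$min_core_gap > -1e-9))                 # no overlap
})

test_that("trajectories are reproducible and continuable", {
  sp <- catch_sequences()
  st <- init_system(list(list(peptide = sp[["CATCH_like(4+)"]], count = 2)),
                    box_side = 70, T_star = 0.2, seed = 5)
  t1 <- run_dmd(st, 2e4, snapshot_every = 5e3)
  t2 <- run_dmd(st, 2e4, snapshot_every = 5e3)
  expect_identical(t1$final_state$positions, t2$final_state$positions)
  expect_identical(t1$times, t2$times)
  # continuation advances time monotonically
  t3 <- run_dmd(t1$final_state, 1e4)
  expect_gt(t3$final_state$time, t1$final_state$time)
})

test_that("the Andersen thermostat drives kinetic temperature to T*", {
  sp <- catch_sequences()
  st <- init_system(list(list(peptide = sp[["CATCH_like(6+)"]], count = 1),
                         list(peptide = sp[["CATCH_like(6-)"]], count = 1)),
                    box_side = 60, T_star = 0.2, seed = 3)
  # start hot: double every velocity, then let the thermostat relax it
  st$velocities <- st$velocities * 2
  tr <- run_dmd(st, 3e5, snapshot_every = 5e3, ghost_rate = 0.02)
  tk <- tr$audit$T_kin
  expect_equal(mean(tail(tk, 20)), 0.2, tolerance = 0.05)
  expect_gt(tr$ghost_count, 100)
})

test_that("head-on core collision happens at (d - sigma) / v", {
  sig <- tab$hs_backbone[["CA"]]           # two CA beads: contact = sigma
  st <- two_bead_state(pos_a = c(50, 50, 50), pos_b = c(60, 50, 50),
                       vel_a = c(0.5, 0, 0), vel_b = c(-0.5, 0, 0),
                       box = 100)
  ev <- next_event(st)
  expect_equal(ev$kind, "core_collision")
  expect_equal(ev$time, (10 - sig) / 1.0, tolerance = 1e-10)
  expect_setequal(c(ev$i, ev$j), c(1, 2))
})

test_that("equal-mass head-on collision exchanges velocities", {
  st <- two_bead_state(pos_a = c(50, 50, 50), pos_b = c(60, 50, 50),
                       vel_a = c(0.5, 0, 0), vel_b = c(-0.2, 0, 0),
                       box = 100)
  tr <- run_dmd(st, 1, ghost_rate = 0)
  v <- tr$final_state$velocities
  expect_equal(v[1, ], c(-0.2, 0, 0), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(v[2, ], c(0.5, 0, 0), tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("well capture from slow approach gives the energy-balance speed", {
  # two phenylalanine sidechain beads: attractive well depth 0.25 eps_HB
  pot <- lookup_pair_potential(tab, "R:F", "R:F")
  m <- tab$masses$sidechain[["F"]]
  mu <- m * m / (m + m)
  v0 <- 1e-4
  st <- two_bead_state(kind_a = "R", kind_b = "R", code_a = "F", code_b = "F",
                       pos_a = c(50, 50, 50),
                       pos_b = c(50 + pot$well_edge + 0.5, 50, 50),
                       vel_a = c(v0, 0, 0), vel_b = c(-v0, 0, 0),
                       box = 100)
  tr <- run_dmd(st, 1, ghost_rate = 0, log_events = 1)
  expect_equal(tr$event_log$kind[1], 1)    # well capture
  v <- tr$final_state$velocities
  b_after <- v[2, 1] - v[1, 1]             # radial relative velocity
  expect_equal(abs(b_after), sqrt((2 * v0)^2 + 2 * pot$well_depth / mu),
               tolerance = 1e-9)
})

test_that("an escape attempt with insufficient radial energy bounces", {
  pot <- lookup_pair_potential(tab, "R:F", "R:F")
  v0 <- 1e-4                                # far too slow to climb 0.25 eps
  mid <- (pot$hard_core + pot$well_edge) / 2
  st <- two_bead_state(kind_a = "R", kind_b = "R", code_a = "F", code_b = "F",
                       pos_a = c(50, 50, 50), pos_b = c(50 + mid, 50, 50),
                       vel_a = c(-v0, 0, 0), vel_b = c(v0, 0, 0),
                       box = 100)
  ke_before <- sum(0.5 * st$topology$beads$mass *
                     rowSums(st$velocities^2))
  tr <- run_dmd(st, 1, ghost_rate = 0, log_events = 1)
  expect_equal(tr$event_log$kind[1], 3)    # well bounce
  v <- tr$final_state$velocities
  ke_after <- sum(0.5 * st$topology$beads$mass * rowSums(v^2))
  expect_equal(ke_after, ke_before, tolerance = 1e-12)
  expect_lt(v[2, 1] - v[1, 1], 0)          # now moving back inward
})

test_that("scheduler matches the brute-force all-pairs oracle", {
  # The oracle scans the 5^3 nearest periodic images, which is exact for
  # any event within two box traversals of relative motion; comparisons
  # are restricted to that window.
  n_match <- 0
  for (seed in 1:130) {
    box <- 30
    st <- make_free_bead_state(10, box = box, seed = seed)
    got <- next_event(st)
    want <- oracle_next_event(st)
    vmax <- sqrt(max(rowSums(st$velocities^2)))
    t_img_bound <- box / vmax
    if (is.null(got)) {
      expect_equal(want$time, Inf)
      next
    }
    if (want$time <= t_img_bound) {
      expect_equal(got$time, want$time, tolerance = 1e-8)
      if (is.finite(want$gap_to_second) && want$gap_to_second > 1e-9) {
        expect_setequal(c(got$i, got$j), c(want$i, want$j))
      }
      n_match <- n_match + 1
    }
  }
  expect_gte(n_match, 100)
})
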