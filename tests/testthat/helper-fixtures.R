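# Shared fixtures and independent oracles for the test suite.

# A state of free beads (no pseudo-bonds, every bead its own chain), placed
# without core overlap; used for event-prediction oracle tests.
make_free_bead_state <- function(n_beads, box, seed, T_star = 0.3,
                                 table = default_interaction_table()) {
  set.seed(seed)
  kinds <- sample(c("NH", "CA", "CO", "R"), n_beads, replace = TRUE)
  codes <- ifelse(kinds == "R",
                  sample(c("F", "K", "E", "Q"), n_beads, replace = TRUE),
                  "Q")
  mass <- ifelse(kinds == "R",
                 table$masses$sidechain[codes],
                 dmdpep:::BACKBONE_MASSES[kinds])
  diam <- ifelse(kinds == "R",
                 table$hs_sidechain[codes],
                 table$hs_backbone[kinds])
  beads <- data.frame(kind = kinds, residue_index = seq_len(n_beads),
                      residue_code = codes, mass = unname(mass),
                      diameter = unname(diam),
                      chain = seq_len(n_beads),
                      global_residue = seq_len(n_beads),
                      stringsAsFactors = FALSE)
  pos <- matrix(NA_real_, n_beads, 3)
  for (i in seq_len(n_beads)) {
    repeat {
      p <- runif(3, 0, box)
      if (i == 1) { pos[i, ] <- p; break }
      d <- sweep(pos[seq_len(i - 1), , drop = FALSE], 2, p)
      d <- d - box * round(d / box)
      contact <- (diam[seq_len(i - 1)] + diam[i]) / 2
      if (all(rowSums(d^2) > (contact + 0.2)^2)) { pos[i, ] <- p; break }
    }
  }
  vel <- matrix(rnorm(3 * n_beads), ncol = 3) * sqrt(T_star / mass)
  topo <- structure(
    list(beads = beads,
         bonds = data.frame(i = integer(0), j = integer(0),
                            ideal = numeric(0), min = numeric(0),
                            max = numeric(0)),
         ca_of = seq_len(n_beads), peptides = list(),
         templates = list(), chain_of = seq_len(n_beads)),
    class = "system_topology")
  structure(
    list(positions = pos, velocities = vel, box_side = box,
         T_star = T_star, time = 0, collision_count = 0,
         hb_partner = rep(NA_integer_, n_beads),
         topology = topo, table = table, seed = seed),
    class = "dmd_state")
}

# Brute-force all-pairs, all-periodic-images scan for the earliest boundary
# event of a state: an independent R re-derivation of the step-potential
# time-of-flight algebra, used as the oracle for the engine's scheduler.
# Scanning the 5^3 nearest lattice images makes the straight-line solution
# exact for any event occurring within two box traversals.
oracle_next_event <- function(state) {
  a <- dmdpep:::engine_args(state)
  n <- nrow(a$pos)
  box <- a$box
  offsets <- as.matrix(expand.grid(kx = -2:2, ky = -2:2, kz = -2:2)) * box
  best <- Inf; second <- Inf; who <- c(NA_integer_, NA_integer_)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      r0 <- a$pos[j, ] - a$pos[i, ]
      r0 <- r0 - box * round(r0 / box)
      w <- a$vel[j, ] - a$vel[i, ]
      v2 <- sum(w * w)
      for (img in seq_len(nrow(offsets))) {
      r <- r0 + offsets[img, ]
      r2 <- sum(r * r); bb <- sum(r * w)
      t_outer <- function(d2) {
        if (bb >= 0) return(Inf)
        disc <- bb^2 - v2 * (r2 - d2)
        if (disc <= 0) return(Inf)
        max(0, (-bb - sqrt(disc)) / v2)
      }
      t_inner <- function(d2) {
        if (v2 == 0) return(Inf)
        disc <- bb^2 - v2 * (r2 - d2)
        if (disc < 0) return(Inf)
        max(0, (-bb + sqrt(disc)) / v2)
      }
      cand <- Inf
      sig2 <- a$sig_mat[a$ptype[i] + 1, a$ptype[j] + 1]^2
      if (r2 <= sig2 * (1 + 1e-9)) {
        if (bb < 0) cand <- 0
      } else {
        cand <- min(cand, t_outer(sig2))
      }
      lam <- a$lam_mat[a$ptype[i] + 1, a$ptype[j] + 1]
      if (lam > 0) {
        cand <- min(cand, if (r2 < lam^2) t_inner(lam^2) else t_outer(lam^2))
      }
      ki <- a$bead_kind[i]; kj <- a$bead_kind[j]
      if ((ki == 0 && kj == 2) || (ki == 2 && kj == 0)) {
        h2 <- a$hb_dist^2
        cand <- min(cand, if (r2 < h2) t_inner(h2) else t_outer(h2))
      }
      if (cand < best) {
        second <- best; best <- cand; who <- c(i, j)
      } else if (cand < second) second <- cand
      }
    }
  }
  list(time = best, i = who[1], j = who[2], gap_to_second = second - best)
}

# Flood-fill connected components, independent of igraph.
flood_fill_membership <- function(n, edges) {
  adj <- vector("list", n)
  if (nrow(edges) > 0) {
    for (k in seq_len(nrow(edges))) {
      a <- edges$i[k]; b <- edges$j[k]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  }
  comp <- integer(n); cur <- 0
  for (s in seq_len(n)) {
    if (comp[s] == 0) {
      cur <- cur + 1
      stack <- s
      while (length(stack) > 0) {
        v <- stack[[1]]; stack <- stack[-1]
        if (comp[v] == 0) {
          comp[v] <- cur
          stack <- c(stack, adj[[v]])
        }
      }
    }
  }
  comp
}

# Canonical form of a partition: order-independent comparison.
canonical_partition <- function(membership) {
  unname(lapply(
    split(seq_along(membership), membership), sort
  ))[order(vapply(split(seq_along(membership), membership),
                  function(s) min(s), numeric(1)))]
}

# Synthetic association graph with prescribed edges (for cluster tests).
make_test_graph <- function(n, edges, charges = rep(0L, n)) {
  ed <- if (nrow(edges) == 0) {
    data.frame(i = integer(0), j = integer(0), n_hbonds = integer(0),
               n_hydrophobic_contacts = integer(0), joined = logical(0))
  } else {
    data.frame(i = edges$i, j = edges$j,
               n_hbonds = if (is.null(edges$n_hbonds)) 0L else edges$n_hbonds,
               n_hydrophobic_contacts = 0L,
               joined = if (is.null(edges$joined)) TRUE else edges$joined)
  }
  structure(
    list(n_peptides = n, species = rep("x", n), charge = charges,
         edges = ed, hb_majority_threshold = NULL, lengths = rep(11L, n)),
    class = "association_graph")
}

# Two-bead state with prescribed kinematics (closed-form event tests).
two_bead_state <- function(kind_a = "CA", kind_b = "CA",
                           code_a = "Q", code_b = "Q",
                           pos_a, pos_b, vel_a, vel_b, box = 200,
                           T_star = 0.2,
                           table = default_interaction_table()) {
  st <- make_free_bead_state(2, box, seed = 1, T_star = T_star, table = table)
  st$topology$beads$kind <- c(kind_a, kind_b)
  st$topology$beads$residue_code <- c(code_a, code_b)
  mass <- ifelse(st$topology$beads$kind == "R",
                 table$masses$sidechain[st$topology$beads$residue_code],
                 dmdpep:::BACKBONE_MASSES[st$topology$beads$kind])
  diam <- ifelse(st$topology$beads$kind == "R",
                 table$hs_sidechain[st$topology$beads$residue_code],
                 table$hs_backbone[st$topology$beads$kind])
  st$topology$beads$mass <- unname(mass)
  st$topology$beads$diameter <- unname(diam)
  st$positions <- rbind(pos_a, pos_b)
  st$velocities <- rbind(vel_a, vel_b)
  st
}
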