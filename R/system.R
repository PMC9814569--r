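#' Peptide concentration in a cubic box
#'
#' @param n_peptides number of peptide molecules.
#' @param box_side box side length (Angstrom).
#' @return concentration in mM.  96 peptides in a 200 Angstrom box give
#'   19.93 mM (the canonical 20 mM co-assembly condition).
#' @export
concentration <- function(n_peptides, box_side) {
  stopifnot(box_side > 0, n_peptides >= 0)
  avogadro <- 6.02214076e23
  vol_litre <- (box_side * 1e-8)^3 / 1000   # A^3 -> cm^3 -> L
  1000 * n_peptides / (avogadro * vol_litre)
}

#' Box side length for a target concentration
#' @param n_peptides number of peptides.
#' @param conc_mM target concentration (mM).
#' @return box side (Angstrom).
#' @export
box_side_for_concentration <- function(n_peptides, conc_mM) {
  stopifnot(n_peptides > 0, conc_mM > 0)
  avogadro <- 6.02214076e23
  vol_litre <- 1000 * n_peptides / (avogadro * conc_mM)
  (vol_litre * 1000)^(1 / 3) * 1e8
}

# Merge per-peptide topologies into one system topology with global indices.
system_topology <- function(peptides, table) {
  tops <- lapply(peptides, build_topology, table = table)
  offset <- 0L
  res_offset <- 0L
  beads <- list(); bonds <- list(); ca <- integer(0); templates <- list()
  for (k in seq_along(tops)) {
    tp <- tops[[k]]
    b <- tp$beads
    b$chain <- k
    b$global_residue <- b$residue_index + res_offset
    beads[[k]] <- b
    bd <- tp$bonds
    bd$i <- bd$i + offset
    bd$j <- bd$j + offset
    bonds[[k]] <- bd
    ca <- c(ca, tp$ca_of + offset)
    templates[[k]] <- tp$template
    offset <- offset + nrow(b)
    res_offset <- res_offset + length(tp$peptide)
  }
  structure(
    list(beads = do.call(rbind, beads), bonds = do.call(rbind, bonds),
         ca_of = ca, peptides = peptides, templates = templates,
         chain_of = rep(seq_along(peptides),
                        vapply(tops, function(t) nrow(t$beads), integer(1)))),
    class = "system_topology"
  )
}

#' @export
print.system_topology <- function(x, ...) {
  cat(sprintf("system_topology: %d peptides, %d beads, %d pseudo-bonds\n",
              length(x$peptides), nrow(x$beads), nrow(x$bonds)))
  invisible(x)
}

random_rotation <- function() {
  # uniform rotation from a random quaternion
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2*(y^2 + z^2), 2*(x*y - w*z),     2*(x*z + w*y),
           2*(x*y + w*z),     1 - 2*(x^2 + z^2), 2*(y*z - w*x),
           2*(x*z - w*y),     2*(y*z + w*x),     1 - 2*(x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}

#' Initialize a simulation state
#'
#' Places peptides in extended conformations at random positions and
#' orientations in a cubic periodic box, rejecting placements that overlap
#' the hard cores of already-placed chains (minimum-image convention), and
#' draws bead velocities from the Maxwell-Boltzmann distribution at the
#' requested reduced temperature with the net momentum removed and the
#' kinetic energy rescaled to match `T_star` exactly.  Deterministic given
#' `seed`.
#'
#' @param species list of `list(peptide = <peptide>, count = <int>)` entries.
#' @param box_side cubic box side (Angstrom).
#' @param T_star reduced temperature (kB T / eps_HB).
#' @param seed integer RNG seed.
#' @param table an `interaction_table`.
#' @param max_retries placement attempts per chain before giving up.
#' @return An object of class `dmd_state`.
#' @examples
#' sp <- catch_sequences()
#' st <- init_system(list(list(peptide = sp[["CATCH_like(6+)"]], count = 2),
#'                        list(peptide = sp[["CATCH_like(6-)"]], count = 2)),
#'                   box_side = 80, T_star = 0.2, seed = 1)
#' @export
init_system <- function(species, box_side, T_star, seed,
                        table = default_interaction_table(),
                        max_retries = 2000) {
  stopifnot(box_side > 0, T_star > 0)
  peptides <- unlist(lapply(species, function(s) {
    stopifnot(inherits(s$peptide, "peptide"), s$count >= 0)
    rep(list(s$peptide), s$count)
  }), recursive = FALSE)
  if (length(peptides) == 0) stop("no peptides to place", call. = FALSE)
  topo <- system_topology(peptides, table)
  n <- nrow(topo$beads)
  set.seed(seed)

  placed <- matrix(numeric(0), ncol = 3)
  placed_diam <- numeric(0)
  pos <- matrix(NA_real_, nrow = n, ncol = 3)
  row0 <- 0L
  for (k in seq_along(peptides)) {
    tmpl <- topo$templates[[k]]
    tmpl <- sweep(tmpl, 2, colMeans(tmpl))
    nb <- nrow(tmpl)
    diam <- topo$beads$diameter[row0 + seq_len(nb)]
    ok <- FALSE
    for (try in seq_len(max_retries)) {
      rot <- random_rotation()
      com <- stats::runif(3, 0, box_side)
      cand <- tmpl %*% t(rot)
      cand <- sweep(cand, 2, com, "+")
      if (nrow(placed) == 0L) { ok <- TRUE; break }
      # minimum-image distances of all candidate beads to all placed beads
      clash <- FALSE
      for (a in seq_len(nb)) {
        d <- sweep(placed, 2, cand[a, ])
        d <- d - box_side * round(d / box_side)
        dist2 <- rowSums(d^2)
        contact <- (placed_diam + diam[a]) / 2
        if (any(dist2 < contact^2)) { clash <- TRUE; break }
      }
      if (!clash) { ok <- TRUE; break }
    }
    if (!ok) {
      stop(sprintf("packing failed: placed %d of %d chains in box %.0f A",
                   k - 1L, length(peptides), box_side), call. = FALSE)
    }
    pos[row0 + seq_len(nb), ] <- cand
    placed <- rbind(placed, cand)
    placed_diam <- c(placed_diam, diam)
    row0 <- row0 + nb
  }
  pos <- pos %% box_side

  m <- topo$beads$mass
  vel <- matrix(stats::rnorm(3 * n), ncol = 3) * sqrt(T_star / m)
  vel <- sweep(vel, 2, colSums(vel * m) / sum(m))   # zero net momentum
  ke <- 0.5 * sum(m * rowSums(vel^2))
  vel <- vel * sqrt(1.5 * n * T_star / ke)          # exact kinetic T*

  structure(
    list(positions = pos, velocities = vel, box_side = box_side,
         T_star = T_star, time = 0, collision_count = 0,
         hb_partner = rep(NA_integer_, n),
         topology = topo, table = table, seed = seed),
    class = "dmd_state"
  )
}

#' @export
print.dmd_state <- function(x, ...) {
  cat(sprintf(paste0("dmd_state: %d peptides (%d beads) in %.0f A box, ",
                     "T* = %.3g, t = %.3g, %.3g mM\n"),
              length(x$topology$peptides), nrow(x$positions), x$box_side,
              x$T_star, x$time,
              concentration(length(x$topology$peptides), x$box_side)))
  invisible(x)
}

# Flatten a state + topology + table into the argument list of the C++ core.
engine_args <- function(state) {
  topo <- state$topology
  table <- state$table
  beads <- topo$beads
  codes_present <- sort(unique(beads$residue_code))
  type_labels <- c("NH", "CA", "CO", paste0("R:", codes_present))
  ptype <- ifelse(beads$kind == "R",
                  match(paste0("R:", beads$residue_code), type_labels),
                  match(beads$kind, type_labels)) - 1L
  nt <- length(type_labels)
  diam_of <- function(lbl) {
    if (lbl %in% c("NH", "CA", "CO")) table$hs_backbone[[lbl]]
    else table$hs_sidechain[[sub("^R:", "", lbl)]]
  }
  diams <- vapply(type_labels, diam_of, numeric(1))
  sig <- outer(diams, diams, function(a, b) (a + b) / 2)
  lam <- matrix(0, nt, nt)
  eps <- matrix(0, nt, nt)
  rr <- grepl("^R:", type_labels)
  for (a in which(rr)) for (b in which(rr)) {
    ca <- sub("^R:", "", type_labels[a])
    cb <- sub("^R:", "", type_labels[b])
    de <- table$sidechain_depth[ca, cb]
    if (de != 0) {
      lam[a, b] <- table$well_width_ratio * sig[a, b]
      eps[a, b] <- de
    }
  }
  hbp <- ifelse(is.na(state$hb_partner), -1L, state$hb_partner - 1L)
  list(
    pos = state$positions, vel = state$velocities,
    mass = beads$mass, box = state$box_side,
    ptype = as.integer(ptype),
    bead_kind = match(beads$kind, c("NH", "CA", "CO", "R")) - 1L,
    chain = as.integer(beads$chain - 1L),
    resi = as.integer(beads$residue_index),
    ca_of = as.integer(topo$ca_of - 1L),
    sig_mat = sig, lam_mat = lam, eps_mat = eps,
    bond_ij = cbind(as.integer(topo$bonds$i - 1L),
                    as.integer(topo$bonds$j - 1L)),
    bond_min = topo$bonds$min, bond_max = topo$bonds$max,
    hb_dist = table$hb$distance, hb_eps = 1.0,
    hb_aux_max = table$hb$aux_max,
    hb_partner0 = as.integer(hbp),
    type_labels = type_labels
  )
}
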