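min_image <- function(d, box) d - box * round(d / box)

pairwise_min_image_dist <- function(A, B, box) {
  # |A_i - B_j| under minimum image; returns length(A) x length(B) matrix
  out <- matrix(0, nrow(A), nrow(B))
  for (a in 1:3) {
    d <- outer(A[, a], B[, a], "-")
    d <- min_image(d, box)
    out <- out + d^2
  }
  sqrt(out)
}

#' Detect backbone hydrogen bonds in a snapshot
#'
#' Geometric hydrogen-bond detection, independent of the engine's bond
#' registry: an NH and a CO bead are candidates when they lie within the
#' hydrogen-bond capture distance and both directional auxiliary constraints
#' hold (the C-alpha flanking the NH within `aux_max` of the CO, and the NH
#' within `aux_max` of the C-alpha flanking the CO).  Pairs within the same
#' or adjacent residues of one chain are excluded.  Each NH and each CO
#' takes part in at most one bond; conflicts are resolved closest-pair
#' first.
#'
#' @param snapshot list with `positions` (n x 3 matrix) and `box_side`
#'   (e.g. from [get_snapshot()]).
#' @param topology a `system_topology`.
#' @param table an `interaction_table`.
#' @return data.frame with columns `nh`, `co` (bead indices), `chain_nh`,
#'   `chain_co`, `distance`.
#' @export
detect_hbonds <- function(snapshot, topology, table) {
  beads <- topology$beads
  pos <- snapshot$positions
  box <- snapshot$box_side
  stopifnot(nrow(pos) == nrow(beads))
  nh <- which(beads$kind == "NH")
  co <- which(beads$kind == "CO")
  if (length(nh) == 0 || length(co) == 0) {
    return(data.frame(nh = integer(0), co = integer(0),
                      chain_nh = integer(0), chain_co = integer(0),
                      distance = numeric(0)))
  }
  D <- pairwise_min_image_dist(pos[nh, , drop = FALSE],
                               pos[co, , drop = FALSE], box)
  cand <- which(D <= table$hb$distance, arr.ind = TRUE)
  if (nrow(cand) > 0) {
    i_nh <- nh[cand[, 1]]
    i_co <- co[cand[, 2]]
    same <- beads$chain[i_nh] == beads$chain[i_co] &
      abs(beads$residue_index[i_nh] - beads$residue_index[i_co]) <= 3
    # directional auxiliary constraints on the flanking C-alpha beads
    ca_nh <- topology$ca_of[i_nh]
    ca_co <- topology$ca_of[i_co]
    d1 <- sqrt(rowSums(min_image(pos[ca_nh, , drop = FALSE] -
                                 pos[i_co, , drop = FALSE], box)^2))
    d2 <- sqrt(rowSums(min_image(pos[i_nh, , drop = FALSE] -
                                 pos[ca_co, , drop = FALSE], box)^2))
    keep <- !same & d1 <= table$hb$aux_max & d2 <= table$hb$aux_max
    cand <- cand[keep, , drop = FALSE]
  }
  if (nrow(cand) == 0) {
    return(data.frame(nh = integer(0), co = integer(0),
                      chain_nh = integer(0), chain_co = integer(0),
                      distance = numeric(0)))
  }
  dd <- D[cand]
  ord <- order(dd)
  used_nh <- logical(length(nh)); used_co <- logical(length(co))
  keep <- logical(length(ord))
  for (k in ord) {
    a <- cand[k, 1]; b <- cand[k, 2]
    if (!used_nh[a] && !used_co[b]) {
      used_nh[a] <- TRUE; used_co[b] <- TRUE; keep[k] <- TRUE
    }
  }
  sel <- cand[keep, , drop = FALSE]
  i_nh <- nh[sel[, 1]]; i_co <- co[sel[, 2]]
  out <- data.frame(nh = i_nh, co = i_co,
                    chain_nh = beads$chain[i_nh],
                    chain_co = beads$chain[i_co],
                    distance = D[sel])
  out[order(out$nh), , drop = FALSE]
}

#' Detect hydrophobic sidechain contacts
#'
#' A hydrophobic contact is a pair of sidechain beads of hydrophobic-class
#' residues on *different* chains lying inside their attractive square well.
#'
#' @inheritParams detect_hbonds
#' @return data.frame with `i`, `j` (bead indices), `chain_i`, `chain_j`,
#'   `distance`.
#' @export
detect_hydrophobic_contacts <- function(snapshot, topology, table) {
  beads <- topology$beads
  pos <- snapshot$positions
  box <- snapshot$box_side
  rt <- residue_table()
  hyd <- which(beads$kind == "R" &
               rt[beads$residue_code, "hydrophobic"])
  empty <- data.frame(i = integer(0), j = integer(0),
                      chain_i = integer(0), chain_j = integer(0),
                      distance = numeric(0))
  if (length(hyd) < 2) return(empty)
  D <- pairwise_min_image_dist(pos[hyd, , drop = FALSE],
                               pos[hyd, , drop = FALSE], box)
  edge <- outer(beads$diameter[hyd], beads$diameter[hyd], "+") / 2 *
    table$well_width_ratio
  cand <- which(D <= edge & upper.tri(D), arr.ind = TRUE)
  if (nrow(cand) == 0) return(empty)
  i <- hyd[cand[, 1]]; j <- hyd[cand[, 2]]
  keep <- beads$chain[i] != beads$chain[j] &
    table$sidechain_depth[cbind(beads$residue_code[i],
                                beads$residue_code[j])] > 0
  data.frame(i = i[keep], j = j[keep],
             chain_i = beads$chain[i[keep]], chain_j = beads$chain[j[keep]],
             distance = D[cand][keep])
}

#' Build the peptide association graph of a snapshot
#'
#' Nodes are peptides; each peptide pair carries its inter-chain backbone
#' hydrogen-bond count and hydrophobic contact count.  A pair is `joined`
#' when a majority of the backbone hydrogen-bonding sites are occupied
#' (count >= `hb_majority_threshold`, default `ceiling((L + 1) / 2)` for
#' L-residue peptides, i.e. 6 for 11-mers) or when there is at least one
#' hydrophobic contact.
#'
#' @inheritParams detect_hbonds
#' @param hb_majority_threshold H-bond count for the majority condition;
#'   `NULL` derives it from the shorter peptide of each pair.
#' @return An object of class `association_graph`: list with `n_peptides`,
#'   `species`, `charge` (per peptide), `edges` (data.frame `i`, `j`,
#'   `n_hbonds`, `n_hydrophobic_contacts`, `joined`) and the threshold used.
#' @export
build_association_graph <- function(snapshot, topology, table,
                                    hb_majority_threshold = NULL) {
  np <- length(topology$peptides)
  hb <- detect_hbonds(snapshot, topology, table)
  ph <- detect_hydrophobic_contacts(snapshot, topology, table)
  lens <- vapply(topology$peptides, length, integer(1))
  key <- function(i, j) paste(pmin(i, j), pmax(i, j))
  counts <- new.env(parent = emptyenv())
  bump <- function(k, field) {
    rec <- counts[[k]]
    if (is.null(rec)) rec <- c(hb = 0, ph = 0)
    rec[field] <- rec[field] + 1
    counts[[k]] <- rec
  }
  inter_hb <- hb[hb$chain_nh != hb$chain_co, , drop = FALSE]
  if (nrow(inter_hb) > 0) {
    for (r in seq_len(nrow(inter_hb)))
      bump(key(inter_hb$chain_nh[r], inter_hb$chain_co[r]), "hb")
  }
  if (nrow(ph) > 0) {
    for (r in seq_len(nrow(ph))) bump(key(ph$chain_i[r], ph$chain_j[r]), "ph")
  }
  keys <- ls(counts)
  edges <- if (length(keys) == 0) {
    data.frame(i = integer(0), j = integer(0), n_hbonds = integer(0),
               n_hydrophobic_contacts = integer(0), joined = logical(0))
  } else {
    ij <- do.call(rbind, strsplit(keys, " "))
    i <- as.integer(ij[, 1]); j <- as.integer(ij[, 2])
    nhb <- vapply(keys, function(k) counts[[k]][["hb"]], numeric(1))
    nph <- vapply(keys, function(k) counts[[k]][["ph"]], numeric(1))
    thr <- if (is.null(hb_majority_threshold)) {
      ceiling((pmin(lens[i], lens[j]) + 1) / 2)
    } else rep(hb_majority_threshold, length(i))
    data.frame(i = i, j = j, n_hbonds = as.integer(nhb),
               n_hydrophobic_contacts = as.integer(nph),
               joined = nhb >= thr | nph >= 1)
  }
  structure(
    list(n_peptides = np,
         species = vapply(topology$peptides, function(p) p$id, character(1)),
         charge = vapply(topology$peptides, net_charge, integer(1)),
         edges = edges,
         hb_majority_threshold = hb_majority_threshold,
         lengths = lens),
    class = "association_graph"
  )
}

#' @export
print.association_graph <- function(x, ...) {
  cat(sprintf("association_graph: %d peptides, %d contact pairs (%d joined)\n",
              x$n_peptides, nrow(x$edges), sum(x$edges$joined)))
  invisible(x)
}

#' Partition peptides into free monomers, oligomers and fibrils
#'
#' Connected components of the joined-pair graph: a component of size 1 is a
#' free peptide, sizes 2-5 are oligomers, and components of more than 5
#' peptides are fibril-class assemblies.
#'
#' @param g an `association_graph`.
#' @return list with `free` (integer vector of peptide indices), `oligomers`
#'   and `fibrils` (lists of integer vectors), and `membership` (component
#'   id per peptide).
#' @export
classify_clusters <- function(g) {
  stopifnot(inherits(g, "association_graph"))
  ed <- g$edges[g$edges$joined, , drop = FALSE]
  gr <- igraph::make_empty_graph(n = g$n_peptides, directed = FALSE)
  if (nrow(ed) > 0) {
    gr <- igraph::add_edges(gr, rbind(ed$i, ed$j))
  }
  comp <- igraph::components(gr)
  mem <- comp$membership
  clusters <- split(seq_len(g$n_peptides), mem)
  sizes <- lengths(clusters)
  list(free = unlist(clusters[sizes == 1], use.names = FALSE),
       oligomers = unname(clusters[sizes >= 2 & sizes <= 5]),
       fibrils = unname(clusters[sizes > 5]),
       membership = as.integer(mem))
}

#' Assembly kinetics of a trajectory
#'
#' Per-snapshot hydrogen-bond count and the free / oligomer / fibril peptide
#' partition.  Counts are reported on the snapshot grid with no smoothing;
#' at every time point `n_free + n_in_oligomers + n_in_fibrils` equals the
#' total number of peptides.
#'
#' @param traj a `dmd_trajectory`.
#' @param hb_majority_threshold see [build_association_graph()].
#' @return An `assembly_kinetics` data.frame with columns `time`, `n_free`,
#'   `n_in_oligomers`, `n_in_fibrils`, `n_hbonds`.
#' @export
kinetics_series <- function(traj, hb_majority_threshold = NULL) {
  stopifnot(inherits(traj, "dmd_trajectory"))
  rows <- lapply(seq_along(traj$times), function(f) {
    snap <- get_snapshot(traj, f)
    g <- build_association_graph(snap, traj$topology, traj$table,
                                 hb_majority_threshold)
    cl <- classify_clusters(g)
    nhb <- nrow(detect_hbonds(snap, traj$topology, traj$table))
    data.frame(time = snap$time,
               n_free = length(cl$free),
               n_in_oligomers = sum(lengths(cl$oligomers)),
               n_in_fibrils = sum(lengths(cl$fibrils)),
               n_hbonds = nhb)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("assembly_kinetics", "data.frame")
  out
}

#' Time to a given level of free-peptide depletion
#'
#' @param kin an `assembly_kinetics` data.frame.
#' @param fraction depletion level: first time at which the free-peptide
#'   count falls to or below `fraction` of the total (default 0.5).
#' @return reduced time, or `NA` if the level is never reached.
#' @export
time_to_depletion <- function(kin, fraction = 0.5) {
  total <- kin$n_free[1] + kin$n_in_oligomers[1] + kin$n_in_fibrils[1]
  hit <- which(kin$n_free <= fraction * total)
  if (length(hit) == 0) return(NA_real_)
  kin$time[hit[1]]
}

#' Strand-order statistics within a fibril cluster
#'
#' Within-sheet neighbours are peptide pairs whose backbone hydrogen-bond
#' count meets the majority threshold (hydrophobic-only contacts connect
#' bilayer leaflets, not strands within a sheet, and are excluded here).
#' Counts neighbouring strand pairs of opposite net charge (the ideal
#' alternating +/- arrangement) versus like-charge mismatches, and the
#' fraction of cationic peptides in the cluster.
#'
#' @param cluster integer vector of peptide indices (e.g. one element of
#'   `classify_clusters(g)$fibrils`).
#' @param g the `association_graph` the cluster came from.
#' @param hb_majority_threshold H-bond count defining a within-sheet
#'   neighbour; `NULL` derives it per pair from the peptide lengths.
#' @return list with `n_alternating_neighbors`, `n_like_charge_neighbors`,
#'   `cation_fraction`.
#' @export
strand_order_stats <- function(cluster, g, hb_majority_threshold = NULL) {
  stopifnot(inherits(g, "association_graph"))
  ed <- g$edges
  ed <- ed[ed$i %in% cluster & ed$j %in% cluster, , drop = FALSE]
  thr <- if (is.null(hb_majority_threshold)) {
    ceiling((pmin(g$lengths[ed$i], g$lengths[ed$j]) + 1) / 2)
  } else rep(hb_majority_threshold, nrow(ed))
  nb <- ed[ed$n_hbonds >= thr, , drop = FALSE]
  qprod <- g$charge[nb$i] * g$charge[nb$j]
  list(n_alternating_neighbors = sum(qprod < 0),
       n_like_charge_neighbors = sum(qprod > 0),
       cation_fraction = mean(g$charge[cluster] > 0))
}
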