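#' Default glutamine/phenylalanine scaffold
#'
#' The 11-mer Q/F scaffold `QQQFQWQFQQQ` used to construct charge variants:
#' a hydrophobic core (F at positions 4 and 8, W at 6) flanked and
#' interleaved by glutamines that can be swapped for charged residues.
#' @return a `peptide`.
#' @export
qf_scaffold <- function() parse_sequence("QQQFQWQFQQQ", id = "QF-scaffold")

default_charge_positions <- list(`2` = c(5, 7),
                                 `4` = c(3, 5, 7, 9),
                                 `6` = c(1, 3, 5, 7, 9, 11))

#' Construct a charge variant of a Q/F scaffold
#'
#' Substitutes lysine (sign `"+"`) or glutamate (sign `"-"`) at glutamine
#' positions of the scaffold, producing a peptide of net charge
#' `+n_charges` or `-n_charges` while leaving the hydrophobic core
#' untouched.
#'
#' @param n_charges number of charged substitutions (must equal
#'   `length(positions)`).
#' @param sign `"+"` or `"-"`.
#' @param scaffold a `peptide` whose Q positions are substituted.
#' @param positions 1-based residue positions to substitute; defaults to the
#'   symmetric placements used for 2, 4 and 6 charges on the 11-mer
#'   scaffold.
#' @return a `peptide` with id `"variant(<n><sign>)"`.
#' @examples
#' sequence_string(make_charge_variant(6, "+"))  # "KQKFKWKFKQK"
#' @export
make_charge_variant <- function(n_charges, sign = c("+", "-"),
                                scaffold = qf_scaffold(),
                                positions = NULL) {
  sign <- match.arg(sign)
  if (is.null(positions)) {
    positions <- default_charge_positions[[as.character(n_charges)]]
    if (is.null(positions)) {
      stop("no default positions for ", n_charges,
           " charges; supply `positions`", call. = FALSE)
    }
  }
  if (length(positions) != n_charges) {
    stop("n_charges (", n_charges, ") must equal length(positions) (",
         length(positions), ")", call. = FALSE)
  }
  codes <- scaffold$residues$code
  if (any(positions < 1 | positions > length(codes))) {
    stop("substitution position out of range", call. = FALSE)
  }
  notq <- positions[codes[positions] != "Q"]
  if (length(notq) > 0) {
    stop("position ", notq[1], " holds ", codes[notq[1]],
         ", not Q; refusing to substitute into the hydrophobic core",
         call. = FALSE)
  }
  codes[positions] <- if (sign == "+") "K" else "E"
  parse_sequence(paste(codes, collapse = ""),
                 id = sprintf("variant(%d%s)", n_charges, sign),
                 n_term_acetylated = scaffold$n_term_acetylated,
                 c_term_amidated = scaffold$c_term_amidated)
}

# translation taking strand k to strand k+1: puts each NH directly above
# the CO of the same residue on the strand below, separated by `spacing`
# along the H-bond (y) axis; exact for every residue by chain periodicity
sheet_shift <- function(topology_one, spacing) {
  tmpl <- topology_one$template
  nres <- nrow(tmpl) / 4
  # the backbone period is two residues, so the NH->CO in-plane offset
  # alternates; the mean offset centres both parities in the capture sphere
  nh <- tmpl[4 * (seq_len(nres) - 1) + 1, , drop = FALSE]
  co <- tmpl[4 * (seq_len(nres) - 1) + 3, , drop = FALSE]
  off <- colMeans(co - nh)
  c(off[1], off[2] + spacing, 0)
}

#' Build an idealized beta-sheet fixture with known ground truth
#'
#' Constructs a single parallel in-register beta-sheet: strand k+1 is strand
#' k translated by one sheet spacing, with each backbone NH placed over the
#' CO of the corresponding residue of the strand below so that every
#' cross-strand NH-CO pair sits inside the hydrogen-bond capture sphere and
#' satisfies the directional constraints by construction.  Optionally a
#' second sheet is apposed hydrophobic-face-to-hydrophobic-face to form a
#' bilayer whose leaflets are connected only by hydrophobic contacts.
#'
#' @param pattern character string of `+` / `-` signs, one per strand
#'   (e.g. `"+-+-+-"`); determines which of `plus` / `minus` each strand is.
#' @param plus,minus the cationic and anionic `peptide` species.
#' @param spacing strand spacing within a sheet (Angstrom).
#' @param bilayer logical: build two apposed sheets (each with
#'   `nchar(pattern)` strands).
#' @param stack_sep backbone-plane separation of the two leaflets
#'   (Angstrom); the default keeps apposed aromatic sidechains inside their
#'   attractive well without core overlap.
#' @param stagger in-plane (x, y) offset of the second leaflet (Angstrom).
#' @param table an `interaction_table`.
#' @param box_margin padding added around the structure to size the box.
#' @return list with `snapshot` (positions + box), `topology`, `table` and
#'   `ground_truth` (expected within-sheet neighbour pairs, expected
#'   H-bonds per neighbour pair, expected cluster sizes).
#' @export
make_ideal_sheet <- function(pattern = "+-+-+-",
                             plus = make_charge_variant(6, "+"),
                             minus = make_charge_variant(6, "-"),
                             spacing = 4.7,
                             bilayer = FALSE,
                             stack_sep = 12,
                             stagger = c(3.5, 2.35),
                             table = default_interaction_table(),
                             box_margin = 30) {
  signs <- strsplit(pattern, "")[[1]]
  if (!all(signs %in% c("+", "-"))) {
    stop("pattern must consist of '+' and '-' only", call. = FALSE)
  }
  n_strands <- length(signs)
  stopifnot(n_strands >= 1)
  peps <- lapply(signs, function(s) if (s == "+") plus else minus)
  if (bilayer) peps <- c(peps, peps)
  topo <- system_topology(peps, table)

  one <- build_topology(plus, table)
  shift <- sheet_shift(one, spacing)
  place_sheet <- function(strand_templates, mirror_z = FALSE, offset = c(0, 0, 0)) {
    out <- list()
    for (k in seq_along(strand_templates)) {
      xyz <- strand_templates[[k]]
      if (mirror_z) xyz[, 3] <- -xyz[, 3]
      xyz <- sweep(xyz, 2, offset + (k - 1) * shift, "+")
      out[[k]] <- xyz
    }
    out
  }
  tmpls <- lapply(peps[seq_len(n_strands)], function(p)
    build_topology(p, table)$template)
  coords <- place_sheet(tmpls)
  if (bilayer) {
    # mirrored leaflet below, hydrophobic faces apposed
    coords2 <- place_sheet(tmpls, mirror_z = TRUE,
                           offset = c(stagger[1], stagger[2], -stack_sep))
    coords <- c(coords, coords2)
  }
  pos <- do.call(rbind, coords)
  # centre in a box with generous margins
  span <- apply(pos, 2, range)
  box <- max(span[2, ] - span[1, ]) + 2 * box_margin
  pos <- sweep(pos, 2, span[1, ] - box_margin, "-")

  n_sheets <- if (bilayer) 2L else 1L
  neighbours <- do.call(rbind, lapply(seq_len(n_sheets), function(s) {
    off <- (s - 1L) * n_strands
    if (n_strands < 2) return(NULL)
    cbind(off + seq_len(n_strands - 1), off + 2:n_strands)
  }))
  total <- n_strands * n_sheets
  list(
    snapshot = list(positions = pos, box_side = box, time = 0),
    topology = topo, table = table,
    ground_truth = list(
      n_strands = total,
      within_sheet_neighbours = neighbours,
      expected_cluster_sizes = total,
      strand_charges = vapply(peps, net_charge, integer(1))
    )
  )
}

#' Synthetic trajectory with exactly known assembly kinetics
#'
#' Builds a trajectory whose cluster time series is known by construction:
#' peptides start as isolated free monomers on a coarse grid, and at each
#' scheduled event two clusters merge; merged clusters are laid out as ideal
#' beta-sheets (strands in joining order), so the geometric analysis
#' recovers the scheduled series exactly.
#'
#' @param schedule data.frame with columns `time`, `a`, `b`: at `time`,
#'   the clusters containing peptides `a` and `b` merge.  Times must be
#'   non-decreasing and each event must merge two distinct clusters.
#' @param peptides list of `peptide` objects (the population).
#' @param table an `interaction_table`.
#' @param spacing strand spacing used for merged clusters (Angstrom).
#' @return a `dmd_trajectory`-compatible object (snapshots at time 0 and
#'   after each event) plus `$expected`: the exact free / oligomer / fibril
#'   counts per snapshot.
#' @export
make_kinetics_toy <- function(schedule, peptides,
                              table = default_interaction_table(),
                              spacing = 4.7) {
  n <- length(peptides)
  stopifnot(n >= 1)
  if (nrow(schedule) > 0) {
    stopifnot(all(c("time", "a", "b") %in% names(schedule)),
              !is.unsorted(schedule$time),
              all(schedule$a >= 1 & schedule$a <= n),
              all(schedule$b >= 1 & schedule$b <= n))
  }
  topo <- system_topology(peptides, table)
  tmpls <- lapply(peptides, function(p) build_topology(p, table)$template)
  shift <- sheet_shift(build_topology(peptides[[1]], table), spacing)
  extent <- max(vapply(tmpls, function(t) max(t) - min(t), numeric(1)))
  cell <- extent + n * spacing + 40    # grid pitch: no cross-cluster contact
  ngrid <- ceiling(n^(1 / 3))
  box <- cell * max(ngrid, 1)
  grid_origin <- function(k) {
    k0 <- k - 1
    cell * c(k0 %% ngrid, (k0 %/% ngrid) %% ngrid, k0 %/% (ngrid^2)) + cell / 4
  }

  membership <- seq_len(n)
  layout_positions <- function() {
    pos <- vector("list", n)
    for (cl in unique(membership)) {
      members <- which(membership == cl)
      org <- grid_origin(cl)
      for (s in seq_along(members)) {
        k <- members[s]
        pos[[k]] <- sweep(tmpls[[k]], 2, org + (s - 1) * shift, "+")
      }
    }
    do.call(rbind, pos)
  }
  count_state <- function() {
    sizes <- tabulate(membership)
    sizes <- sizes[sizes > 0]
    c(n_free = sum(sizes == 1),
      n_in_oligomers = sum(sizes[sizes >= 2 & sizes <= 5]),
      n_in_fibrils = sum(sizes[sizes > 5]))
  }

  times <- 0
  snaps <- list(layout_positions())
  expected <- list(count_state())
  if (nrow(schedule) > 0) {
    for (r in seq_len(nrow(schedule))) {
      ca <- membership[schedule$a[r]]
      cb <- membership[schedule$b[r]]
      if (ca == cb) {
        stop("schedule event ", r, " merges a cluster with itself",
             call. = FALSE)
      }
      membership[membership == cb] <- ca
      times <- c(times, schedule$time[r])
      snaps <- c(snaps, list(layout_positions()))
      expected <- c(expected, list(count_state()))
    }
  }
  structure(
    list(times = times,
         snapshots = snaps,
         hb_registry = rep(list(NULL), length(times)),
         audit = NULL,
         box_side = box,
         topology = topo,
         table = table,
         T_star = NA_real_,
         collision_count = 0, ghost_count = 0, pass_count = 0,
         reduced_time = max(times),
         expected = do.call(rbind, expected),
         final_state = NULL),
    class = "dmd_trajectory"
  )
}
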