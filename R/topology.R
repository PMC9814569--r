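#' Canonical extended-chain template coordinates
#'
#' Builds an idealized extended (beta-strand-like) conformation for a
#' peptide: the three backbone beads per residue (NH, C-alpha, CO) walk a
#' planar zigzag with fixed virtual bond lengths and angles, and each
#' sidechain bead R is displaced perpendicular to the backbone plane from
#' its C-alpha, alternating sides residue by residue as in a beta-strand.
#' All pseudo-bond ideal lengths used by the engine are *measured from this
#' template*, which makes the geometry self-consistent by construction.
#'
#' @param p a `peptide`.
#' @param table an `interaction_table` (supplies C-alpha-to-sidechain
#'   distances).
#' @return numeric matrix `(4 * length(p)) x 3` of coordinates (Angstrom),
#'   rows ordered NH, CA, CO, R per residue.
#' @keywords internal
chain_template <- function(p, table) {
  n <- length(p)
  # virtual bond lengths (A) and angles (deg) of the backbone walk
  len <- c(NH_CA = 1.46, CA_CO = 1.51, CO_NH = 1.33)
  ang <- c(CA = 111, CO = 116, NH = 122)
  xyz <- matrix(0, nrow = 4 * n, ncol = 3)
  phi <- 0            # walk direction in the xy-plane
  sgn <- 1            # zigzag turn alternation
  pos <- c(0, 0)
  bb_rows <- integer(0)
  k <- 0
  for (r in seq_len(n)) {
    for (bead in c("NH", "CA", "CO")) {
      k <- k + 1
      row <- 4 * (r - 1) + match(bead, c("NH", "CA", "CO"))
      if (k > 1) {
        step <- switch(bead, NH = len["CO_NH"], CA = len["NH_CA"],
                       CO = len["CA_CO"])
        pos <- pos + step * c(cos(phi), sin(phi))
      }
      xyz[row, 1:2] <- pos
      # turn at this atom before the next bond
      turn <- (180 - ang[[bead]]) * pi / 180
      phi <- phi + sgn * turn
      sgn <- -sgn
      bb_rows <- c(bb_rows, row)
    }
    # sidechain bead: out-of-plane offset from the C-alpha, alternating sides
    ca_row <- 4 * (r - 1) + 2
    d <- unname(table$ca_r_distance[p$residues$code[r]])
    xyz[4 * (r - 1) + 4, ] <- xyz[ca_row, ] + c(0, 0, d * (-1)^(r - 1))
  }
  # rotate the chain axis onto x so that sheet fixtures can stack strands
  # along y; the walk above runs diagonally in the xy-plane
  if (n >= 2) {
    ca1 <- xyz[2, 1:2]
    can <- xyz[4 * (n - 1) + 2, 1:2]
    u <- can - ca1
    th <- atan2(u[2], u[1])
    rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    xyz[, 1:2] <- xyz[, 1:2] %*% rot
  }
  xyz
}

#' Build the bead topology of a peptide
#'
#' Expands a peptide into its four-bead-per-residue representation: beads
#' NH, C-alpha, CO and sidechain R per residue, plus the pseudo-bond set that
#' maintains chain geometry under hard constraints:
#' covalent neighbours (NH-CA, CA-CO, CO-NH of the next residue),
#' next-nearest-neighbour angular constraints (NH-CO within a residue,
#' CA-NH, CO-CA and CA-CA across the peptide bond, which lock the trans
#' peptide bond while leaving the phi/psi torsions free), and the three
#' sidechain attachment bonds (R-NH, R-CA, R-CO).  Ideal bond lengths are
#' measured from the extended-chain template; each bond may fluctuate by
#' `table$bond_tolerance` of its ideal length.
#'
#' @param p a `peptide`.
#' @param table an `interaction_table`.
#' @return An object of class `bead_topology`: list with
#'   `beads` (data.frame: `kind`, `residue_index`, `residue_code`, `mass`,
#'   `diameter`), `bonds` (data.frame: `i`, `j`, `ideal`, `min`, `max`),
#'   `template` (coordinate matrix), `ca_of` (index of each bead's residue
#'   C-alpha), and the source `peptide`.
#' @examples
#' top <- build_topology(parse_sequence("QQKFKWKFKQQ"),
#'                       default_interaction_table())
#' nrow(top$beads)  # 44 beads for an 11-mer
#' @export
build_topology <- function(p, table) {
  stopifnot(inherits(p, "peptide"), inherits(table, "interaction_table"))
  n <- length(p)
  codes <- p$residues$code
  missing <- setdiff(codes, names(table$hs_sidechain))
  if (length(missing) > 0) {
    stop("no geometry in interaction table for residue(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  kinds <- rep(c("NH", "CA", "CO", "R"), n)
  resi <- rep(seq_len(n), each = 4)
  mass <- ifelse(kinds == "R",
                 table$masses$sidechain[codes[resi]],
                 BACKBONE_MASSES[kinds])
  diam <- ifelse(kinds == "R",
                 table$hs_sidechain[codes[resi]],
                 table$hs_backbone[kinds])
  beads <- data.frame(kind = kinds, residue_index = resi,
                      residue_code = codes[resi],
                      mass = unname(mass), diameter = unname(diam),
                      stringsAsFactors = FALSE)
  xyz <- chain_template(p, table)

  idx <- function(r, bead) 4 * (r - 1) + match(bead, c("NH", "CA", "CO", "R"))
  bi <- integer(0); bj <- integer(0)
  add <- function(i, j) { bi <<- c(bi, i); bj <<- c(bj, j) }
  for (r in seq_len(n)) {
    add(idx(r, "NH"), idx(r, "CA"))
    add(idx(r, "CA"), idx(r, "CO"))
    add(idx(r, "NH"), idx(r, "CO"))          # angular constraint at CA
    add(idx(r, "R"),  idx(r, "NH"))
    add(idx(r, "R"),  idx(r, "CA"))
    add(idx(r, "R"),  idx(r, "CO"))
    if (r < n) {
      add(idx(r, "CO"), idx(r + 1, "NH"))    # peptide bond
      add(idx(r, "CA"), idx(r + 1, "NH"))    # angular constraint at CO
      add(idx(r, "CO"), idx(r + 1, "CA"))    # angular constraint at NH
      add(idx(r, "CA"), idx(r + 1, "CA"))    # trans-lock
    }
  }
  ideal <- sqrt(rowSums((xyz[bi, , drop = FALSE] - xyz[bj, , drop = FALSE])^2))
  tol <- table$bond_tolerance
  bonds <- data.frame(i = bi, j = bj, ideal = ideal,
                      min = ideal * (1 - tol), max = ideal * (1 + tol))
  structure(
    list(beads = beads, bonds = bonds, template = xyz,
         ca_of = 4 * (resi - 1) + 2, peptide = p),
    class = "bead_topology"
  )
}

#' @export
print.bead_topology <- function(x, ...) {
  cat(sprintf("bead_topology: %d residues, %d beads, %d pseudo-bonds (%s)\n",
              length(x$peptide), nrow(x$beads), nrow(x$bonds),
              x$peptide$id))
  invisible(x)
}
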