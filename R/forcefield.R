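#' Default square-well interaction table
#'
#' Builds the package's default coarse-grained interaction table for the
#' four-bead chain model (backbone NH, C-alpha, CO beads plus one sidechain
#' bead R per residue).  The published intermediate-resolution parameter sets
#' for this kind of model discriminate hundreds of residue-pair-specific well
#' widths and depths; those tables are not bundled here.  Instead the default
#' is an explicit class-based reduction:
#'
#' * hydrophobic-hydrophobic sidechains: attractive well, depth
#'   `eps_hydrophobic` (default 0.25 in units of the hydrogen-bond energy);
#' * cationic-anionic sidechains: attractive well, depth `eps_charge`
#'   (default 0.35);
#' * like-charged sidechains (cationic-cationic, anionic-anionic): repulsive
#'   shoulder of the same magnitude;
#' * polar-polar sidechains (S, T, N, Q, Y, H, C): weak attractive well,
#'   depth `eps_polar` (default 0.08);
#' * every other non-bonded pair: pure hard sphere;
#' * backbone NH-CO: directional hydrogen-bond well of depth 1 (the energy
#'   unit), capture distance `hb_distance`, with auxiliary distance windows
#'   on the flanking C-alpha beads enforcing directionality.
#'
#' All well edges sit at `well_width_ratio` times the pair's hard-sphere
#' contact distance.  Depths are expressed in units of the hydrogen-bond
#' energy `eps_hb_kJmol` (12.47 kJ/mol), which also defines the reduced
#' temperature scale.  A complete user-supplied table can replace the
#' sidechain wells via [read_interaction_table()].
#'
#' @param eps_hydrophobic,eps_charge,eps_polar well depths, units of the
#'   hydrogen-bond energy.
#' @param well_width_ratio well edge / hard-sphere contact distance.
#' @param hb_distance hydrogen-bond capture distance (Angstrom).
#' @param hb_aux_max auxiliary directional constraint: the C-alpha flanking
#'   the NH (resp. CO) bead must lie within this distance (Angstrom) of the
#'   partner bead for a bond to form.
#' @param eps_hb_kJmol hydrogen-bond well depth in kJ/mol.
#' @param bond_tolerance fractional fluctuation allowed on pseudo-bonds.
#' @return An object of class `interaction_table`.
#' @examples
#' tab <- default_interaction_table()
#' lookup_pair_potential(tab, "R:K", "R:E")  # attractive charge pair
#' @export
default_interaction_table <- function(eps_hydrophobic = 0.25,
                                      eps_charge = 0.35,
                                      eps_polar = 0.08,
                                      well_width_ratio = 1.5,
                                      hb_distance = 5.0,
                                      hb_aux_max = 6.5,
                                      eps_hb_kJmol = 12.47,
                                      bond_tolerance = 0.02375) {
  stopifnot(well_width_ratio > 1, hb_distance > 0, eps_hb_kJmol > 0,
            bond_tolerance > 0, bond_tolerance < 0.1)
  rt <- residue_table()
  # signed depth in eps_HB units: positive = attractive (U = -depth inside)
  pair_depth <- function(ca, cb) {
    if (ca == "cationic" && cb == "anionic") return(eps_charge)
    if (ca == "anionic" && cb == "cationic") return(eps_charge)
    if (ca %in% c("cationic", "anionic") && ca == cb) return(-eps_charge)
    if (ca == "hydrophobic" && cb == "hydrophobic") return(eps_hydrophobic)
    if (ca == "polar" && cb == "polar") return(eps_polar)
    0
  }
  codes <- rt$code
  depth <- outer(seq_along(codes), seq_along(codes),
                 Vectorize(function(i, j) {
                   pair_depth(rt$interaction_class[i], rt$interaction_class[j])
                 }))
  dimnames(depth) <- list(codes, codes)
  structure(
    list(
      hs_backbone = BACKBONE_DIAMETERS,
      hs_sidechain = stats::setNames(rt$sidechain_diameter, codes),
      sidechain_depth = depth,          # eps_HB units, signed
      well_width_ratio = well_width_ratio,
      hb = list(eps_kJmol = eps_hb_kJmol,
                distance = hb_distance,
                aux_max = hb_aux_max),
      bond_tolerance = bond_tolerance,
      masses = list(backbone = BACKBONE_MASSES,
                    sidechain = stats::setNames(rt$sidechain_mass, codes)),
      ca_r_distance = stats::setNames(rt$ca_r_distance, codes)
    ),
    class = "interaction_table"
  )
}

#' @export
print.interaction_table <- function(x, ...) {
  nz <- sum(x$sidechain_depth != 0 & upper.tri(x$sidechain_depth, diag = TRUE))
  cat("interaction_table:\n",
      sprintf("  eps_HB = %.2f kJ/mol, H-bond capture %.2f A (aux <= %.2f A)\n",
              x$hb$eps_kJmol, x$hb$distance, x$hb$aux_max),
      sprintf("  %d non-zero sidechain wells, well edge = %.2f x contact\n",
              nz, x$well_width_ratio),
      sprintf("  pseudo-bond tolerance %.3f%%\n", 100 * x$bond_tolerance))
  invisible(x)
}

parse_bead_label <- function(label) {
  if (label %in% c("NH", "CA", "CO")) {
    return(list(kind = label, residue = NA_character_))
  }
  if (grepl("^R:", label)) {
    return(list(kind = "R", residue = sub("^R:", "", label)))
  }
  stop("bead label must be 'NH', 'CA', 'CO' or 'R:<code>' (got '",
       label, "')", call. = FALSE)
}

#' Look up the step potential acting between two bead types
#'
#' Sidechain-sidechain pairs return a square well (or a pure hard sphere when
#' the class depth is zero); backbone NH-CO returns the hydrogen-bond well
#' descriptor; every other pair is a pure hard sphere.  The lookup is
#' symmetric in its arguments.
#'
#' @param table an `interaction_table`.
#' @param bead_a,bead_b bead labels: `"NH"`, `"CA"`, `"CO"` or `"R:<code>"`
#'   (e.g. `"R:F"` for a phenylalanine sidechain).
#' @return list with `kind` (`"hard_sphere"`, `"square_well"`, `"hbond"`),
#'   `hard_core` (Angstrom), `well_edge` (Angstrom or `NA`), `well_depth`
#'   (magnitude, eps_HB units) and `sign` (`"attractive"`, `"repulsive"` or
#'   `"none"`).
#' @export
lookup_pair_potential <- function(table, bead_a, bead_b) {
  stopifnot(inherits(table, "interaction_table"))
  a <- parse_bead_label(bead_a)
  b <- parse_bead_label(bead_b)
  diam <- function(x) {
    if (x$kind == "R") {
      d <- table$hs_sidechain[x$residue]
      if (is.na(d)) stop("no geometry for residue '", x$residue, "'",
                         call. = FALSE)
      unname(d)
    } else unname(table$hs_backbone[x$kind])
  }
  contact <- (diam(a) + diam(b)) / 2
  if (a$kind == "R" && b$kind == "R") {
    eps <- table$sidechain_depth[a$residue, b$residue]
    if (eps == 0) {
      return(list(kind = "hard_sphere", hard_core = contact,
                  well_edge = NA_real_, well_depth = 0, sign = "none"))
    }
    return(list(kind = "square_well", hard_core = contact,
                well_edge = table$well_width_ratio * contact,
                well_depth = abs(eps),
                sign = if (eps > 0) "attractive" else "repulsive"))
  }
  kinds <- sort(c(a$kind, b$kind))
  if (identical(kinds, c("CO", "NH"))) {
    return(list(kind = "hbond", hard_core = contact,
                well_edge = table$hb$distance, well_depth = 1,
                sign = "attractive"))
  }
  list(kind = "hard_sphere", hard_core = contact,
       well_edge = NA_real_, well_depth = 0, sign = "none")
}

#' Reduced temperature from kelvin
#'
#' The reduced temperature of the model is `T* = kB * T / eps_HB` with the
#' hydrogen-bond energy `eps_HB` = 12.47 kJ/mol by default and
#' kB = 8.31446e-3 kJ/(mol K).
#'
#' @param T_kelvin absolute temperature (K), > 0.
#' @param eps_hb_kJmol hydrogen-bond energy (kJ/mol).
#' @return dimensionless reduced temperature.
#' @seealso [kelvin_from_reduced()] for the inverse.
#' @export
reduced_temperature <- function(T_kelvin, eps_hb_kJmol = 12.47) {
  if (!is.numeric(T_kelvin) || any(T_kelvin <= 0)) {
    stop("temperature must be positive", call. = FALSE)
  }
  KB_KJMOL * T_kelvin / eps_hb_kJmol
}

#' @rdname reduced_temperature
#' @param T_star reduced temperature, > 0.
#' @export
kelvin_from_reduced <- function(T_star, eps_hb_kJmol = 12.47) {
  if (!is.numeric(T_star) || any(T_star <= 0)) {
    stop("reduced temperature must be positive", call. = FALSE)
  }
  T_star * eps_hb_kJmol / KB_KJMOL
}

KB_KJMOL <- 8.31446e-3  # Boltzmann constant x Avogadro, kJ/(mol K)

#' Write / read a sidechain well table as plain text
#'
#' The tabular text format is whitespace-delimited with a version header
#' line, one row per unordered residue pair:
#' `code_a code_b well_width_ratio depth`, with `depth` the signed well depth
#' in eps_HB units (positive attractive, negative repulsive).  Reading
#' returns a copy of `base` with the listed entries overridden, so a partial
#' file patches the default table and a complete file replaces it.
#'
#' @param table an `interaction_table`.
#' @param path file path.
#' @param base table whose entries are overridden (default the package
#'   default table).
#' @return `write_interaction_table` returns `path` invisibly;
#'   `read_interaction_table` returns an `interaction_table`.
#' @export
write_interaction_table <- function(table, path) {
  stopifnot(inherits(table, "interaction_table"))
  codes <- colnames(table$sidechain_depth)
  rows <- c("# dmdpep sidechain well table v1",
            "# code_a code_b well_width_ratio depth_epsHB")
  for (i in seq_along(codes)) {
    for (j in i:length(codes)) {
      d <- table$sidechain_depth[i, j]
      if (d != 0) {
        rows <- c(rows, sprintf("%s %s %.6g %.6g", codes[i], codes[j],
                                table$well_width_ratio, d))
      }
    }
  }
  writeLines(rows, path)
  invisible(path)
}

#' @rdname write_interaction_table
#' @export
read_interaction_table <- function(path, base = default_interaction_table()) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !grepl("^#", lines)]
  tab <- base
  for (ln in lines) {
    f <- strsplit(ln, "\\s+")[[1]]
    if (length(f) != 4) stop("malformed table row: '", ln, "'", call. = FALSE)
    a <- f[1]; b <- f[2]
    if (!a %in% colnames(tab$sidechain_depth) ||
        !b %in% colnames(tab$sidechain_depth)) {
      stop("unknown residue code in table row: '", ln, "'", call. = FALSE)
    }
    tab$well_width_ratio <- as.numeric(f[3])
    tab$sidechain_depth[a, b] <- as.numeric(f[4])
    tab$sidechain_depth[b, a] <- as.numeric(f[4])
  }
  tab
}
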