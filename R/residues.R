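#' Residue parameter table
#'
#' Per-residue parameters used by the sequence and force-field layers: formal
#' charge at pH 7.4, hydrophobicity class, coarse-grained sidechain bead
#' geometry (hard-sphere diameter and the distance of the sidechain centroid
#' from the alpha-carbon) and sidechain bead mass.  Covers the 20 standard
#' amino acids plus ornithine (one-letter code `O`), a +1 cationic residue
#' that appears in charge-complementary designs such as P11-14.
#'
#' Charges are formal integer charges at neutral pH: K, R and O are +1, E and
#' D are -1, histidine is treated as neutral, everything else 0.  The
#' hydrophobic class is a boolean (F, W, L, I, V, M, A, P); it drives the
#' hydrophobic square-well class in [default_interaction_table()] and the
#' hydrophobic-contact rule in the assembly analysis.  Geometry and masses
#' are class-based coarse-grained values, not a published parameter set; a
#' complete external table can be supplied through
#' [read_interaction_table()].
#'
#' @return A data.frame with one row per residue code and columns
#'   `code`, `name`, `formal_charge`, `hydrophobic`, `interaction_class`
#'   (one of `"hydrophobic"`, `"cationic"`, `"anionic"`, `"polar"`,
#'   `"other"`), `sidechain_diameter` (Angstrom), `ca_r_distance` (Angstrom,
#'   alpha-carbon to sidechain centroid), `sidechain_mass` (amu).
#' @examples
#' rt <- residue_table()
#' rt[rt$code %in% c("K", "E", "Q", "F"), ]
#' @export
residue_table <- function() {
  df <- data.frame(
    code = c("A","R","N","D","C","Q","E","G","H","I",
             "L","K","M","F","P","S","T","W","Y","V","O"),
    name = c("alanine","arginine","asparagine","aspartate","cysteine",
             "glutamine","glutamate","glycine","histidine","isoleucine",
             "leucine","lysine","methionine","phenylalanine","proline",
             "serine","threonine","tryptophan","tyrosine","valine",
             "ornithine"),
    formal_charge = c(0, 1, 0, -1, 0, 0, -1, 0, 0, 0,
                      0, 1, 0, 0, 0, 0, 0, 0, 0, 0, 1),
    hydrophobic = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
                    FALSE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, FALSE,
                    FALSE, TRUE, FALSE, TRUE, FALSE),
    sidechain_diameter = c(2.7, 4.3, 3.7, 3.6, 3.2, 4.0, 3.9, 2.2, 4.2, 4.1,
                           4.1, 4.0, 4.1, 4.4, 3.7, 3.0, 3.4, 4.8, 4.5, 3.8,
                           3.8),
    ca_r_distance = c(1.6, 4.1, 2.5, 2.5, 2.0, 3.1, 3.1, 1.2, 3.1, 2.6,
                      2.6, 3.5, 2.9, 3.4, 1.9, 1.9, 1.9, 3.9, 3.5, 2.0,
                      3.0),
    sidechain_mass = c(15, 100, 58, 59, 47, 72, 73, 1, 81, 57,
                       57, 72, 75, 91, 42, 31, 45, 130, 107, 43,
                       58),
    stringsAsFactors = FALSE
  )
  cls <- ifelse(df$formal_charge > 0, "cationic",
         ifelse(df$formal_charge < 0, "anionic",
         ifelse(df$hydrophobic, "hydrophobic",
         ifelse(df$code %in% c("S","T","N","Q","Y","H","C"), "polar",
                "other"))))
  df$interaction_class <- cls
  rownames(df) <- df$code
  df
}

# Backbone bead masses (amu): united NH, C-alpha(H), C=O groups.
BACKBONE_MASSES <- c(NH = 15, CA = 13, CO = 28)

# Backbone hard-sphere diameters (Angstrom).
BACKBONE_DIAMETERS <- c(NH = 3.3, CA = 3.7, CO = 4.0)

#' Look up one residue
#'
#' @param code one-letter residue code.
#' @return A one-row list of residue parameters (see [residue_table()]).
#' @keywords internal
residue_spec <- function(code) {
  rt <- residue_table()
  if (!code %in% rt$code) {
    stop("unknown residue code '", code, "'", call. = FALSE)
  }
  as.list(rt[code, ])
}
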