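#' Write a trajectory as multi-frame XYZ
#'
#' Bead names combine bead type and residue code (e.g. `NH`, `CA`, `CO`,
#' `RF` for a phenylalanine sidechain); the comment line carries the
#' snapshot time and box side.
#'
#' @param traj a `dmd_trajectory`.
#' @param path output file.
#' @param frames snapshot indices to write (default all).
#' @return `path`, invisibly.
#' @export
write_xyz <- function(traj, path, frames = seq_along(traj$times)) {
  beads <- traj$topology$beads
  nm <- ifelse(beads$kind == "R", paste0("R", beads$residue_code), beads$kind)
  con <- file(path, "w")
  on.exit(close(con))
  for (f in frames) {
    p <- traj$snapshots[[f]]
    writeLines(as.character(nrow(p)), con)
    writeLines(sprintf("t= %.6g box= %.6g", traj$times[f], traj$box_side),
               con)
    writeLines(sprintf("%-4s %12.4f %12.4f %12.4f", nm, p[, 1], p[, 2],
                       p[, 3]), con)
  }
  invisible(path)
}

#' Write one snapshot as a PDB file
#'
#' One chain per peptide (chain identifiers cycle A-Z, a-z, 0-9), bead kind
#' as atom name, residue code as residue name.  Coarse-grained beads are
#' written as HETATM-free ATOM records for easy visualization.
#'
#' @param snapshot list with `positions` and `box_side` (see
#'   [get_snapshot()]).
#' @param topology a `system_topology`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pdb_snapshot <- function(snapshot, topology, path) {
  beads <- topology$beads
  p <- snapshot$positions
  chains <- c(LETTERS, letters, as.character(0:9))
  ch <- chains[(beads$chain - 1) %% length(chains) + 1]
  lines <- c(
    sprintf("CRYST1%9.3f%9.3f%9.3f  90.00  90.00  90.00 P 1           1",
            snapshot$box_side, snapshot$box_side, snapshot$box_side),
    sprintf("ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
            seq_len(nrow(p)) %% 100000,
            substr(beads$kind, 1, 4),
            beads$residue_code, ch, beads$residue_index %% 10000,
            p[, 1], p[, 2], p[, 3]),
    "END")
  writeLines(lines, path)
  invisible(path)
}

#' Write an assembly-kinetics series as CSV
#'
#' @param kin an `assembly_kinetics` data.frame from [kinetics_series()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_kinetics_csv <- function(kin, path) {
  utils::write.csv(as.data.frame(kin), path, row.names = FALSE)
  invisible(path)
}
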