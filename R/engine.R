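#' Run event-driven dynamics
#'
#' Advances the system by `n_collisions` impulsive events (hard-core and
#' bond-limit collisions, well captures/escapes/bounces, hydrogen-bond
#' formation and rupture).  Ghost collisions of the Andersen thermostat and
#' conditional pass-through crossings of the hydrogen-bond capture sphere
#' are bookkept separately and do not count against the budget.  Between
#' events every bead moves ballistically; the dynamics is exact up to
#' floating-point error, so total energy (kinetic plus occupied well depths)
#' and momentum are conserved between thermostat events.
#'
#' All internal quantities are reduced: energies in units of the
#' hydrogen-bond well depth eps_HB, lengths in Angstrom, masses in amu, so
#' reduced time is Angstrom * sqrt(amu / eps_HB).  The returned trajectory
#' also carries a microsecond estimate obtained from the production-scale
#' calibration of roughly 200e9 collisions per 16 us for a 96-peptide
#' system; it is a reporting convenience only.
#'
#' @param state a `dmd_state` from [init_system()] (or the `final_state` of
#'   a previous run, for continuation).
#' @param n_collisions impulsive-event budget (>= 0).
#' @param snapshot_every collisions between trajectory snapshots (0 = only
#'   endpoint snapshots).
#' @param ghost_rate Andersen thermostat rate, ghost collisions per bead per
#'   reduced time unit; 0 disables the thermostat (microcanonical).
#' @param seed RNG seed for the thermostat stream (defaults to the state's
#'   seed).
#' @param log_events record the first `log_events` resolved impulsive events
#'   (for diagnostics and oracle tests).
#' @return An object of class `dmd_trajectory`: snapshot times, positions,
#'   per-snapshot energy audit (kinetic, incremental and recomputed
#'   potential energy, kinetic temperature, momentum, minimal core gap),
#'   hydrogen-bond registry per snapshot, event counts, and `final_state`
#'   (a `dmd_state` usable for continuation).
#' @export
run_dmd <- function(state, n_collisions, snapshot_every = 0,
                    ghost_rate = 0.02, seed = NULL, log_events = 0) {
  stopifnot(inherits(state, "dmd_state"), n_collisions >= 0)
  if (is.null(seed)) seed <- state$seed
  a <- engine_args(state)
  res <- dmd_run_cpp(a$pos, a$vel, a$mass, a$box, a$ptype, a$bead_kind,
                     a$chain, a$resi, a$ca_of, a$sig_mat, a$lam_mat,
                     a$eps_mat, a$bond_ij, a$bond_min, a$bond_max,
                     a$hb_dist, a$hb_eps, a$hb_aux_max, a$hb_partner0,
                     state$T_star, ghost_rate,
                     as.double(n_collisions), as.double(snapshot_every),
                     as.integer(seed), as.integer(log_events),
                     FALSE, state$time)
  build_trajectory(state, res)
}

build_trajectory <- function(state, res) {
  n <- nrow(state$positions)
  final_state <- state
  final_state$positions <- res$positions
  final_state$velocities <- res$velocities
  final_state$time <- res$time
  final_state$collision_count <- state$collision_count + res$collision_count
  hbp <- res$hb_partner
  final_state$hb_partner <- ifelse(hbp < 0, NA_integer_, hbp + 1L)
  kin <- data.frame(
    time = res$snapshot_time,
    KE = res$snapshot_KE,
    U = res$snapshot_U_incremental,
    U_exact = res$snapshot_U_exact,
    T_kin = 2 * res$snapshot_KE / (3 * n),
    min_core_gap = res$snapshot_min_gap,
    n_hbonds = res$snapshot_n_hbonds,
    collisions = res$snapshot_collisions,
    ghosts = res$snapshot_ghosts
  )
  kin <- cbind(kin, res$snapshot_momentum)
  structure(
    list(times = res$snapshot_time,
         snapshots = res$snapshots,
         hb_registry = lapply(res$snapshot_hb_partner,
                              function(h) ifelse(h < 0, NA_integer_, h + 1L)),
         audit = kin,
         box_side = state$box_side,
         topology = state$topology,
         table = state$table,
         T_star = state$T_star,
         collision_count = res$collision_count,
         ghost_count = res$ghost_count,
         pass_count = res$pass_count,
         pop_count = res$pop_count,
         cross_count = res$cross_count,
         reduced_time = res$time - state$time,
         microseconds_estimate = res$collision_count * 16 / 200e9,
         event_log = res$event_log,
         used_cell_list = res$used_cell_list,
         final_state = final_state),
    class = "dmd_trajectory"
  )
}

#' @export
print.dmd_trajectory <- function(x, ...) {
  cat(sprintf(paste0("dmd_trajectory: %d snapshots over %.4g reduced time, ",
                     "%.0f collisions (+%.0f ghost, +%.0f pass-through)\n"),
              length(x$times), x$reduced_time, x$collision_count,
              x$ghost_count, x$pass_count))
  if (!is.null(x$audit)) {
    cat(sprintf("  final H-bonds: %d; kinetic T end: %.4f (target T* %.3f)\n",
                utils::tail(x$audit$n_hbonds, 1),
                utils::tail(x$audit$T_kin, 1), x$T_star))
  }
  invisible(x)
}

#' Extract one snapshot from a trajectory
#'
#' @param traj a `dmd_trajectory`.
#' @param frame snapshot index (default: last).
#' @return list with `positions`, `box_side`, `time`, `hb_partner`.
#' @export
get_snapshot <- function(traj, frame = length(traj$times)) {
  stopifnot(inherits(traj, "dmd_trajectory"),
            frame >= 1, frame <= length(traj$times))
  list(positions = traj$snapshots[[frame]], box_side = traj$box_side,
       time = traj$times[frame], hb_partner = traj$hb_registry[[frame]])
}

#' Peek at the next event of a state
#'
#' Runs the event scheduler just far enough to resolve the first impulsive
#' or conditional boundary event (thermostat disabled) and reports it.  Used
#' for scheduler verification against brute-force event scans.
#'
#' @param state a `dmd_state`.
#' @return list with `time` (absolute reduced time), `kind` (label), and
#'   bead indices `i`, `j`; or `NULL` if no event will ever occur.
#' @export
next_event <- function(state) {
  stopifnot(inherits(state, "dmd_state"))
  a <- engine_args(state)
  res <- dmd_run_cpp(a$pos, a$vel, a$mass, a$box, a$ptype, a$bead_kind,
                     a$chain, a$resi, a$ca_of, a$sig_mat, a$lam_mat,
                     a$eps_mat, a$bond_ij, a$bond_min, a$bond_max,
                     a$hb_dist, a$hb_eps, a$hb_aux_max, a$hb_partner0,
                     state$T_star, 0, 1e15, 0, state$seed, 1L, TRUE,
                     state$time)
  lg <- res$event_log
  if (nrow(lg) == 0) return(NULL)
  labels <- c("core_collision", "well_capture", "well_escape", "well_bounce",
              "bond_limit", "hb_form", "hb_break", "hb_bounce",
              "pass_through")
  list(time = lg$time[1], kind = labels[lg$kind[1] + 1],
       i = lg$i[1], j = lg$j[1])
}

#' Kinetic temperature of a state
#' @param state a `dmd_state`.
#' @return instantaneous reduced kinetic temperature 2 KE / (3 N).
#' @export
kinetic_temperature <- function(state) {
  m <- state$topology$beads$mass
  ke <- 0.5 * sum(m * rowSums(state$velocities^2))
  2 * ke / (3 * nrow(state$velocities))
}
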