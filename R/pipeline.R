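#' Species composition for a scaled-down assembly scenario
#'
#' Maps a short system name to a species list: `"2"`, `"4"`, `"6"` are
#' equimolar charge-complementary pairs of the bundled synthetic
#' CATCH-like variants (half cationic, half anionic), `"2+"`, `"2-"`,
#' `"4+"`, `"4-"`, `"6+"`, `"6-"` are single-species systems, and `"Q11"`
#' is the zwitterionic parent peptide.
#'
#' @param system system name.
#' @param n_peptides total peptide count (split evenly for pairs).
#' @return list of `list(peptide, count)` entries.
#' @export
mini_system_species <- function(system, n_peptides = 16) {
  sp <- catch_sequences()
  pick <- function(tag) sp[[paste0("CATCH_like(", tag, ")")]]
  if (system %in% c("2", "4", "6")) {
    half <- n_peptides %/% 2
    return(list(list(peptide = pick(paste0(system, "+")), count = half),
                list(peptide = pick(paste0(system, "-")),
                     count = n_peptides - half)))
  }
  if (system %in% c("2+", "2-", "4+", "4-", "6+", "6-")) {
    return(list(list(peptide = pick(system), count = n_peptides)))
  }
  if (system == "Q11") {
    return(list(list(peptide = sp[["Q11"]], count = n_peptides)))
  }
  stop("unknown system '", system, "'", call. = FALSE)
}

#' Run one scaled-down assembly scenario
#'
#' Convenience wrapper: choose the species composition, size the box for
#' the requested concentration, initialize, simulate, and compute the
#' assembly kinetics.  The defaults define the package's desk-scale
#' scenario: 16 peptides at 20 mM, reduced temperature 0.20 and an event
#' budget of 2e7 collisions, a deliberately reduced version of
#' production-scale co-assembly simulations (96 peptides, 2e11 collisions);
#' results at this scale are qualitative.
#'
#' @param system system name (see [mini_system_species()]).
#' @param seed RNG seed.
#' @param n_peptides total peptides.
#' @param T_star reduced temperature.
#' @param conc_mM peptide concentration (mM); sets the box side.
#' @param n_collisions impulsive-event budget.
#' @param snapshot_every collisions between snapshots (default: 20
#'   snapshots over the run).
#' @param table an `interaction_table`.
#' @param ghost_rate Andersen thermostat rate (per bead per reduced time).
#' @return list with `trajectory` (`dmd_trajectory`), `kinetics`
#'   (`assembly_kinetics`) and the scenario parameters.
#' @export
run_mini_assembly <- function(system, seed, n_peptides = 16, T_star = 0.20,
                              conc_mM = 20, n_collisions = 2e7,
                              snapshot_every = NULL,
                              table = default_interaction_table(),
                              ghost_rate = 0.02) {
  species <- mini_system_species(system, n_peptides)
  box <- box_side_for_concentration(n_peptides, conc_mM)
  if (is.null(snapshot_every)) snapshot_every <- max(1, n_collisions %/% 20)
  st <- init_system(species, box, T_star, seed, table = table)
  tr <- run_dmd(st, n_collisions, snapshot_every = snapshot_every,
                ghost_rate = ghost_rate, seed = seed)
  kin <- kinetics_series(tr)
  list(trajectory = tr, kinetics = kin,
       system = system, seed = seed, n_peptides = n_peptides,
       T_star = T_star, conc_mM = conc_mM, box_side = box,
       n_collisions = n_collisions)
}

#' Run the generate / build / run / analyze pipeline
#'
#' Executes the requested stages in order for one scenario, writing outputs
#' under `out_dir` and returning a run manifest.  Stages:
#' `generate` writes the species FASTA; `build` writes the initial state as
#' PDB; `run` simulates and writes the trajectory as multi-frame XYZ;
#' `analyze` writes the kinetics CSV and a per-cluster report CSV of the
#' final snapshot.
#'
#' @param config list with entries `system` (see [mini_system_species()]),
#'   `seed`, and optionally `n_peptides`, `T_star`, `conc_mM`,
#'   `n_collisions`, `snapshot_every`, `ghost_rate`,
#'   `stages` (subset of generate/build/run/analyze, in order).
#' @param out_dir output directory (created if missing).
#' @return the run manifest: config, seeds, package version, per-stage
#'   output paths and runtime stats.  On stage failure the manifest
#'   records the failing stage and the error, with partial outputs listed.
#' @export
run_pipeline <- function(config, out_dir = tempfile("dmdpep_run_")) {
  stopifnot(is.list(config), !is.null(config$system), !is.null(config$seed))
  defaults <- list(n_peptides = 16, T_star = 0.20, conc_mM = 20,
                   n_collisions = 2e7, snapshot_every = NULL,
                   ghost_rate = 0.02,
                   stages = c("generate", "build", "run", "analyze"))
  config <- utils::modifyList(defaults, config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = config,
                   package_version = as.character(
                     utils::packageVersion("dmdpep")),
                   out_dir = out_dir, outputs = list(), runtime = list(),
                   failed_stage = NULL)
  prefix <- file.path(out_dir, paste0(gsub("[^0-9A-Za-z+-]", "_",
                                           config$system),
                                      "_seed", config$seed))
  table <- default_interaction_table()
  species <- mini_system_species(config$system, config$n_peptides)
  state <- NULL; traj <- NULL
  for (stage in config$stages) {
    t0 <- proc.time()[["elapsed"]]
    ok <- tryCatch({
      if (stage == "generate") {
        f <- paste0(prefix, "_species.fasta")
        peps <- lapply(species, `[[`, "peptide")
        ids <- vapply(peps, `[[`, character(1), "id")
        write_peptide_fasta(peps[!duplicated(ids)], f)
        manifest$outputs$generate <- f
      } else if (stage == "build") {
        box <- box_side_for_concentration(config$n_peptides, config$conc_mM)
        state <- init_system(species, box, config$T_star, config$seed,
                              table = table)
        f <- paste0(prefix, "_initial.pdb")
        write_pdb_snapshot(list(positions = state$positions,
                                box_side = state$box_side),
                           state$topology, f)
        manifest$outputs$build <- f
      } else if (stage == "run") {
        if (is.null(state)) stop("run stage requires build stage")
        se <- config$snapshot_every
        if (is.null(se)) se <- max(1, config$n_collisions %/% 20)
        traj <- run_dmd(state, config$n_collisions, snapshot_every = se,
                         ghost_rate = config$ghost_rate, seed = config$seed)
        f <- paste0(prefix, "_traj.xyz")
        write_xyz(traj, f)
        manifest$outputs$run <- f
      } else if (stage == "analyze") {
        if (is.null(traj)) stop("analyze stage requires run stage")
        kin <- kinetics_series(traj)
        f1 <- paste0(prefix, "_kinetics.csv")
        write_kinetics_csv(kin, f1)
        snap <- get_snapshot(traj)
        g <- build_association_graph(snap, traj$topology, traj$table)
        cl <- classify_clusters(g)
        sizes <- tabulate(cl$membership)
        report <- data.frame(
          cluster = seq_along(sizes)[sizes > 0],
          size = sizes[sizes > 0],
          class = cut(sizes[sizes > 0], c(0, 1, 5, Inf),
                      labels = c("free", "oligomer", "fibril")))
        f2 <- paste0(prefix, "_clusters.csv")
        utils::write.csv(report, f2, row.names = FALSE)
        manifest$outputs$analyze <- c(f1, f2)
      } else stop("unknown stage '", stage, "'")
      TRUE
    }, error = function(e) {
      manifest$failed_stage <<- list(stage = stage,
                                     message = conditionMessage(e))
      FALSE
    })
    manifest$runtime[[stage]] <- proc.time()[["elapsed"]] - t0
    if (!ok) break
  }
  manifest_path <- paste0(prefix, "_manifest.json")
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(manifest[c("config", "package_version", "outputs",
                                    "failed_stage")],
                         manifest_path, auto_unbox = TRUE, null = "null",
                         force = TRUE)
    manifest$outputs$manifest <- manifest_path
  }
  manifest
}

#' Read a pipeline configuration file
#'
#' YAML configuration with the keys of [run_pipeline()]'s config list:
#' `system` (or `species`: a FASTA path plus per-species counts), `seed`,
#' `n_peptides`, `T_star`, `conc_mM`, `n_collisions`, `snapshot_every`,
#' `ghost_rate`, `stages`.
#'
#' @param path YAML file.
#' @return a config list for [run_pipeline()].
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' writeLines(c("system: '6'", "seed: 1", "n_collisions: 1e5"), f)
#' read_run_config(f)
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  num <- intersect(names(cfg),
                   c("seed", "n_peptides", "T_star", "conc_mM",
                     "n_collisions", "snapshot_every", "ghost_rate"))
  for (k in num) cfg[[k]] <- as.numeric(cfg[[k]])
  if (!is.null(cfg$seed)) cfg$seed <- as.integer(cfg$seed)
  cfg
}
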