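#' Pipeline configuration
#'
#' Collects every knob of the full pair-interaction pipeline with the
#' standard defaults: configuration sampling with 144 x 144 x 16
#' configurations per distance on a 3-16 A grid in 0.5 A steps,
#' coordination MD with 400 solvent molecules, 10,000 equilibration plus
#' 400,000 production steps and a 1 A catch radius, all at 298 K.
#'
#' @param molecules named list of parameterized `molecule`s, or a character
#'   vector of fixture names.
#' @param model an [energy_model()].
#' @param n_sphere,n_rot,r_start,r_end,r_step sampling settings.
#' @param n_solvent,equilibration_steps,production_steps,record_interval,
#'   catch_radius,cutoff,thermostat_rate MD settings.
#' @param temperature temperature (K).
#' @param seed RNG seed for the stochastic stages.
#' @param rho_dpd,diagonal_value,max_deviation,zij_one particle-set
#'   settings.
#' @param out_dir optional output directory for CSV/JSON artifacts.
#' @return A validated `pipeline_config`.
#' @export
pipeline_config <- function(molecules, model = energy_model(),
                            n_sphere = 144, n_rot = 16, r_start = 3,
                            r_end = 16, r_step = 0.5, n_solvent = 400,
                            equilibration_steps = 10000,
                            production_steps = 400000,
                            record_interval = 100, catch_radius = 1,
                            cutoff = 9, thermostat_rate = 25,
                            temperature = 298, seed = 1, rho_dpd = 3,
                            diagonal_value = 24.83, max_deviation = 20,
                            zij_one = FALSE, out_dir = NULL) {
  if (is.character(molecules))
    molecules <- setNames(lapply(molecules, fixture), molecules)
  if (is.null(names(molecules)) || any(!nzchar(names(molecules))))
    stop("molecules must be named")
  stopifnot(length(molecules) >= 1, n_sphere >= 1, n_rot >= 1,
            r_start < r_end, r_step > 0, n_solvent >= 1,
            temperature > 0, catch_radius >= 0)
  for (m in molecules)
    if (!is_parameterized(m))
      stop("molecule '", m$name, "' is not parameterized")
  keep <- c("molecules", "model", "n_sphere", "n_rot", "r_start", "r_end",
            "r_step", "n_solvent", "equilibration_steps",
            "production_steps", "record_interval", "catch_radius",
            "cutoff", "thermostat_rate", "temperature", "seed", "rho_dpd",
            "diagonal_value", "max_deviation", "zij_one", "out_dir")
  structure(mget(keep), class = "pipeline_config")
}

#' Run the full pair-interaction pipeline
#'
#' For every unordered molecule pair: coarse distance scan, two-stage
#' refinement of the sampled minimum, Boltzmann-averaged curves and local
#' dimer optimization. For every ordered pair: a coordination MD run (a
#' single molecule i among `n_solvent` molecules j). The resulting E_min
#' and <E>_min matrices and the Z matrix are mapped to Flory-Huggins
#' parameters and a scaled DPD particle set. Stage failures are recorded
#' per pair and do not abort the remaining pairs.
#'
#' @param config a [pipeline_config()].
#' @param progress print per-stage progress.
#' @return A result bundle: energy matrices, coordination matrix, particle
#'   set, per-pair details, failures, the resolved config and timings.
#' @export
run_pipeline <- function(config, progress = interactive()) {
  stopifnot(inherits(config, "pipeline_config"))
  mols <- config$molecules
  nm <- names(mols)
  k <- length(mols)
  say <- function(...) if (progress) message(sprintf(...))
  t0 <- Sys.time()
  e_min <- e_mean_min <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  z <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  pairs <- list()
  failures <- list()

  for (i in seq_len(k)) for (j in i:k) {
    key <- paste(nm[i], nm[j], sep = "-")
    say("dimer scan %s", key)
    res <- tryCatch({
      prm <- pair_params(mols[[i]], mols[[j]], config$model)
      scan <- scan_distance_grid(mols[[i]], mols[[j]], config$r_start,
                                 config$r_end, config$r_step,
                                 config$n_sphere, config$n_rot,
                                 config$temperature, params = prm)
      ref <- refine_minimum(scan, mols[[i]], mols[[j]], params = prm)
      cfg <- enumerate_configurations(mols[[i]], mols[[j]],
                                      ref$best$distance, config$n_sphere,
                                      config$n_rot, params = prm)
      best <- which.min(cfg$energies)
      cstar <- dimer_coordinates(cfg, best)
      opt <- optimize_dimer(mols[[i]], mols[[j]], cstar$coords_i,
                            cstar$coords_j, backend = "rigid",
                            params = prm)
      list(scan = scan, refined = ref$best, curves = extract_curves(scan),
           e_cstar = ref$best$e_cstar, e_mean_min = min(scan$e_mean),
           optimized = opt)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[key]] <- conditionMessage(res)
      next
    }
    pairs[[key]] <- res
    e_min[i, j] <- e_min[j, i] <- res$optimized$e_min
    e_mean_min[i, j] <- e_mean_min[j, i] <- res$e_mean_min
  }

  for (i in seq_len(k)) for (j in seq_len(k)) {
    key <- paste0("Z:", nm[i], "|", nm[j])
    say("coordination MD %s in %s", nm[i], nm[j])
    res <- tryCatch({
      vol <- vabc_volume(mols[[j]])
      edge <- box_edge_length(config$n_solvent, vol)
      box <- build_solvent_box(mols[[j]], config$n_solvent, edge,
                               seed = config$seed)
      box <- insert_solute(box, mols[[i]], seed = config$seed + 1)
      box <- minimize_box(box, md_settings(cutoff = config$cutoff),
                          config$model)
      st <- md_settings(temperature = config$temperature,
                        equilibration_steps = config$equilibration_steps,
                        production_steps = config$production_steps,
                        record_interval = config$record_interval,
                        thermostat_rate = config$thermostat_rate,
                        cutoff = min(config$cutoff, box$edge / 2 * 0.99))
      traj <- run_md(box, st, config$model, seed = config$seed + 2)
      estimate_coordination_number(
        traj, neighbor_criterion(config$catch_radius))$z
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[key]] <- conditionMessage(res)
      next
    }
    z[i, j] <- res
  }

  particle_set <- NULL
  if (!anyNA(e_mean_min) && !anyNA(z)) {
    particle_set <- tryCatch(
      build_particle_set(e_mean_min, z, config$temperature,
                         config$rho_dpd, config$diagonal_value,
                         config$max_deviation, config$zij_one),
      error = function(e) {
        failures[["particle_set"]] <- conditionMessage(e)
        NULL
      })
  }

  bundle <- list(e_min = e_min, e_mean_min = e_mean_min, z = z,
                 particle_set = particle_set, pairs = pairs,
                 failures = failures,
                 config = config,
                 elapsed_s = as.numeric(difftime(Sys.time(), t0,
                                                 units = "secs")),
                 version = as.character(utils::packageVersion("mesopair")))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    for (key in names(pairs))
      write.csv(pairs[[key]]$curves,
                file.path(config$out_dir, paste0("curves_", key, ".csv")),
                row.names = FALSE)
    if (!is.null(particle_set))
      export_particle_set(particle_set,
                          file.path(config$out_dir, "particle_set"))
    summary <- list(
      e_min = e_min, e_mean_min = e_mean_min, z = z,
      failures = failures, seed = config$seed,
      temperature = config$temperature,
      n_sphere = config$n_sphere, n_rot = config$n_rot,
      version = bundle$version)
    jsonlite::write_json(summary,
                         file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  bundle
}

#' Self-test of the installed pipeline
#'
#' Runs a reduced water-water configuration scan (16 x 16 x 4
#' configurations, 2-8 A grid in 0.5 A steps) and a short solvent-box MD,
#' then checks structural invariants: configuration counts, the
#' <E> >= E^C* inequality at every distance, agreement of the cell-index
#' and brute-force neighbor counts, and thermostat sanity.
#'
#' @param progress print the individual check results.
#' @return Invisibly `TRUE` when every check passes; otherwise the failed
#'   checks are reported in the error.
#' @export
test_pipeline <- function(progress = TRUE) {
  checks <- character()
  fail <- character()
  note <- function(name, ok) {
    if (progress) message(sprintf("%-45s %s", name, ifelse(ok, "ok", "FAIL")))
    if (!ok) fail <<- c(fail, name)
    checks <<- c(checks, name)
  }
  w <- fixture("H2O")
  cfg <- enumerate_configurations(w, w, 3.0, n_sphere = 16, n_rot = 4)
  note("configuration count 16*16*4",
       length(cfg$energies) == 16L * 16L * 4L)
  scan <- scan_distance_grid(w, w, 2.0, 8.0, 0.5, n_sphere = 16,
                             n_rot = 4)
  note("scan grid has 13 distances", nrow(scan) == 13L)
  note("<E> >= E^C* at every distance",
       all(scan$e_mean >= scan$e_cstar - 1e-9))
  note("curves table matches scan rows",
       nrow(extract_curves(scan)) == nrow(scan))
  edge <- box_edge_length(27, vabc_volume(w))
  box <- build_solvent_box(w, 27, edge, seed = 7)
  box <- insert_solute(box, fixture("MeOH"), seed = 8)
  st <- md_settings(equilibration_steps = 100, production_steps = 400,
                    record_interval = 50, cutoff = edge / 2 * 0.9)
  traj <- run_md(box, st, seed = 9)
  note("MD recorded 8 frames", length(traj$frames) == 8L)
  crit <- neighbor_criterion()
  counts <- vapply(traj$frames, function(f) {
    bf <- count_neighbors_bruteforce(f, traj$molecule_index,
                                     traj$solute_index, traj$elements,
                                     crit, traj$edge)
    ci <- suppressMessages(
      count_neighbors_cellindex(f, traj$molecule_index,
                                traj$solute_index, traj$elements,
                                crit, traj$edge))
    bf == ci
  }, logical(1))
  note("cell-index equals brute force on all frames", all(counts))
  tk <- kinetic_temperature(traj)
  note("kinetic temperature finite and positive", all(is.finite(tk) & tk > 0))
  if (length(fail))
    stop("self-test failures: ", paste(fail, collapse = "; "))
  invisible(TRUE)
}
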