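#' Per-molecule box volume from density and molar mass
#'
#' Volume occupied by one molecule in the neat liquid,
#' M / (rho N_A), in A^3. The defaults are liquid water at 298 K
#' (rho = 0.997047 g/cm^3, M = 18.01528 g/mol), giving 30.00 A^3: the
#' reference ratio against the water van der Waals volume of 17.35 A^3 that
#' fixes the density of every simulation box.
#'
#' @param density liquid density in g/cm^3.
#' @param molar_mass molar mass in g/mol.
#' @return Volume per molecule in A^3.
#' @export
box_volume_per_molecule <- function(density = 0.997047,
                                    molar_mass = 18.01528) {
  stopifnot(density > 0, molar_mass > 0)
  molar_mass / (density * 6.02214076e23) * 1e24
}

#' Edge length of a cubic simulation box
#'
#' a = cbrt(N * (V_box^H2O / V_vdW^H2O) * V_vdW^X): every molecule X gets
#' the same ratio of occupied to van der Waals volume as water
#' (30.00 / 17.35 at 298 K).
#'
#' @param n_molecules number of molecules in the box.
#' @param vdw_volume van der Waals volume of the molecule (A^3), e.g. from
#'   [vabc_volume()].
#' @param water_box_volume,water_vdw_volume the water reference volumes
#'   (A^3).
#' @return Cubic edge length in Angstrom.
#' @examples
#' box_edge_length(400, 17.35)  # 22.894 A for 400 waters
#' @export
box_edge_length <- function(n_molecules, vdw_volume,
                            water_box_volume = 30.00,
                            water_vdw_volume = 17.35) {
  if (n_molecules <= 0 || vdw_volume <= 0)
    stop("inputs must be positive")
  (n_molecules * (water_box_volume / water_vdw_volume) * vdw_volume)^(1 / 3)
}

#' MD settings
#'
#' @param timestep integration step (fs).
#' @param temperature target temperature (K).
#' @param equilibration_steps discarded initial steps.
#' @param production_steps recorded steps after equilibration.
#' @param record_interval record a frame every this many production steps.
#' @param thermostat_rate Andersen collision frequency per atom (ps^-1).
#' @param cutoff non-bonded cutoff (Angstrom).
#' @return A validated list of class `md_settings`.
#' @export
md_settings <- function(timestep = 1, temperature = 298,
                        equilibration_steps = 10000,
                        production_steps = 400000,
                        record_interval = 100, thermostat_rate = 25,
                        cutoff = 9) {
  stopifnot(timestep > 0, temperature > 0, equilibration_steps >= 0,
            production_steps >= 0, record_interval > 0,
            thermostat_rate >= 0, cutoff > 0)
  if (production_steps > 0 && record_interval > production_steps)
    stop("record_interval exceeds production_steps")
  structure(list(timestep = timestep, temperature = temperature,
                 equilibration_steps = as.integer(equilibration_steps),
                 production_steps = as.integer(production_steps),
                 record_interval = as.integer(record_interval),
                 thermostat_rate = thermostat_rate, cutoff = cutoff),
            class = "md_settings")
}

#' Build a solvent box
#'
#' Places `n` copies of a parameterized molecule on a jittered cubic
#' sublattice with random orientations inside a cubic box, rejecting
#' placements that bring any two atoms of different molecules closer than
#' `min_dist`.
#'
#' @param mol_j parameterized solvent `molecule`.
#' @param n number of copies.
#' @param edge box edge (Angstrom), e.g. from [box_edge_length()].
#' @param seed optional RNG seed for reproducible packing.
#' @param min_dist minimum allowed interatomic spacing between molecules
#'   (Angstrom).
#' @param max_retries placement retries per molecule before giving up.
#' @return A `simulation_box`.
#' @export
build_solvent_box <- function(mol_j, n, edge, seed = NULL, min_dist = 1.5,
                              max_retries = 200) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n >= 1, edge > 0)
  ncell <- ceiling(n^(1 / 3))
  cell <- edge / ncell
  sites <- as.matrix(expand.grid(seq_len(ncell), seq_len(ncell),
                                 seq_len(ncell)))
  sites <- (sites - 0.5) * cell
  ## spread the n molecules over the ncell^3 available sites
  sites <- sites[sample(nrow(sites), n), , drop = FALSE]
  local <- centered_coords(mol_j)
  placed <- vector("list", n)
  all_pos <- NULL
  for (m in seq_len(n)) {
    best <- NULL
    best_d <- -Inf
    for (try in seq_len(max_retries)) {
      rot <- random_rotation()
      jitter <- runif(3, -0.2, 0.2) * cell
      xyz <- local %*% t(rot) +
        matrix(sites[m, ] + jitter, nrow(local), 3, byrow = TRUE)
      xyz <- xyz %% edge
      d <- if (is.null(all_pos)) Inf else
        min_cross_distance(xyz, all_pos, edge)
      if (d > best_d) {
        best <- xyz
        best_d <- d
      }
      if (d >= min_dist) break
    }
    placed[[m]] <- best
    all_pos <- rbind(all_pos, best)
  }
  box <- new_simulation_box(mol_j, placed, edge)
  relax_contacts(box, min_dist, max_sweeps = max_retries)
}

## rigid-body push-apart: translate clashing molecules pairwise along their
## center line until no intermolecular atom pair is closer than min_dist
relax_contacts <- function(box, min_dist, max_sweeps = 200) {
  edge <- box$edge
  idx <- box$molecule_index
  nmol <- length(box$molecules)
  for (sweep in seq_len(max_sweeps)) {
    pos <- box$positions
    d2 <- 0
    for (k in 1:3) {
      dk <- outer(pos[, k], pos[, k], `-`)
      dk <- dk - edge * round(dk / edge)
      d2 <- d2 + dk^2
    }
    same <- outer(idx, idx, `==`)
    d2[same] <- Inf
    viol <- which(d2 < min_dist^2, arr.ind = TRUE)
    viol <- viol[viol[, 1] < viol[, 2], , drop = FALSE]
    if (!nrow(viol)) return(box)
    shift <- matrix(0, nmol, 3)
    centers <- t(vapply(seq_len(nmol), function(m)
      colMeans(pos[idx == m, , drop = FALSE]), numeric(3)))
    for (v in seq_len(nrow(viol))) {
      mi <- idx[viol[v, 1]]
      mj <- idx[viol[v, 2]]
      dc <- centers[mi, ] - centers[mj, ]
      dc <- dc - edge * round(dc / edge)
      nrm <- sqrt(sum(dc^2))
      dir <- if (nrm < 1e-8) c(1, 0, 0) else dc / nrm
      gap <- min_dist - sqrt(d2[viol[v, 1], viol[v, 2]])
      shift[mi, ] <- shift[mi, ] + dir * (gap / 2 + 0.02)
      shift[mj, ] <- shift[mj, ] - dir * (gap / 2 + 0.02)
    }
    for (m in seq_len(nmol)) {
      rows <- idx == m
      box$positions[rows, ] <-
        (pos[rows, , drop = FALSE] +
           matrix(shift[m, ], sum(rows), 3, byrow = TRUE)) %% edge
    }
  }
  stop("could not reach an intermolecular spacing of ", min_dist,
       " A; increase the edge length")
}

random_rotation <- function() {
  ## uniform random rotation from a normalized quaternion
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

min_cross_distance <- function(a, b, edge) {
  d <- 0
  best <- Inf
  for (k in 1:3) {
    dk <- outer(a[, k], b[, k], `-`)
    dk <- dk - edge * round(dk / edge)
    d <- d + dk^2
  }
  sqrt(min(d))
}

new_simulation_box <- function(template, placed, edge,
                               molecules = NULL, solute_index = NA_integer_) {
  if (is.null(molecules)) molecules <- rep(list(template), length(placed))
  n_per <- vapply(molecules, n_atoms, 1L)
  structure(list(
    edge = edge,
    molecules = molecules,
    positions = do.call(rbind, placed),
    molecule_index = rep(seq_along(placed), n_per),
    solute_index = solute_index,
    velocities = NULL
  ), class = "simulation_box")
}

#' @export
print.simulation_box <- function(x, ...) {
  cat(sprintf("<simulation_box> edge %.3f A, %d molecules, %d atoms%s\n",
              x$edge, length(x$molecules), nrow(x$positions),
              if (!is.na(x$solute_index))
                sprintf(", solute = molecule %d", x$solute_index) else ""))
  invisible(x)
}

box_atom_field <- function(box, field) {
  unlist(lapply(box$molecules, `[[`, field), use.names = FALSE)
}

#' Insert a single solute molecule into a solvent box
#'
#' The solute is placed at the box center; solvent molecules with any atom
#' closer than `overlap_factor` times the van der Waals radius sum to any
#' solute atom are removed, which keeps the packing density sane (the
#' removal count is recorded in the `removed` attribute).
#'
#' @param box a `simulation_box`.
#' @param mol_i parameterized solute `molecule`.
#' @param seed optional RNG seed for the solute orientation.
#' @param overlap_factor removal threshold as a fraction of the vdW sum.
#' @return The box with the solute appended as the last molecule and
#'   `solute_index` set.
#' @export
insert_solute <- function(box, mol_i, seed = NULL, overlap_factor = 0.8) {
  if (!is.null(seed)) set.seed(seed)
  center <- rep(box$edge / 2, 3)
  xyz <- centered_coords(mol_i) %*% t(random_rotation()) +
    matrix(center, n_atoms(mol_i), 3, byrow = TRUE)
  rad_solute <- bondi_radii(mol_i$elements)
  keep <- logical(length(box$molecules))
  for (m in seq_along(box$molecules)) {
    rows <- box$molecule_index == m
    pos <- box$positions[rows, , drop = FALSE]
    rad <- bondi_radii(box$molecules[[m]]$elements)
    thr <- outer(rad_solute, rad, `+`) * overlap_factor
    d <- 0
    for (k in 1:3) {
      dk <- outer(xyz[, k], pos[, k], `-`)
      dk <- dk - box$edge * round(dk / box$edge)
      d <- d + dk^2
    }
    keep[m] <- all(sqrt(d) >= thr)
  }
  placed <- lapply(which(keep), function(m)
    box$positions[box$molecule_index == m, , drop = FALSE])
  molecules <- box$molecules[keep]
  placed <- c(placed, list(xyz %% box$edge))
  molecules <- c(molecules, list(mol_i))
  out <- new_simulation_box(NULL, placed, box$edge, molecules = molecules,
                            solute_index = length(molecules))
  attr(out, "removed") <- sum(!keep)
  out
}

#' Minimize a simulation box
#'
#' Gradient-based local minimization (L-BFGS with the analytic gradient) of
#' the box potential: intermolecular LJ + Coulomb within the cutoff plus
#' the intramolecular harmonic restraints. The returned configuration never
#' has a higher energy than the input; used to remove atomic contacts that
#' would destabilize the integrator.
#'
#' @param box a `simulation_box` (parameterized molecules).
#' @param settings `md_settings` (reserved; the minimizer itself runs
#'   without a cutoff so the objective stays continuous).
#' @param model `energy_model` providing the Coulomb constant/dielectric.
#' @param max_iter iteration cap per L-BFGS pass.
#' @param force_tol restart threshold on the maximum force component
#'   (kcal/mol/A).
#' @param cutoff non-bonded cutoff for the objective; the default -1 means
#'   no cutoff (a truncated potential is discontinuous at the cutoff,
#'   which breaks line searches).
#' @return The box with minimized positions; energies before/after in
#'   attributes.
#' @export
minimize_box <- function(box, settings = md_settings(),
                         model = energy_model(), max_iter = 200,
                         force_tol = 1, cutoff = -1) {
  sys <- box_system(box)
  n <- nrow(box$positions)
  eval_at <- function(p) {
    cpp_box_energy_gradient(matrix(p, n, 3), sys$molecule_index,
                            sys$sigma, sys$epsilon, sys$charges,
                            sys$restraints, box$edge, cutoff,
                            model$coulomb_constant, model$dielectric,
                            TRUE)
  }
  p0 <- as.numeric(box$positions)
  e0 <- eval_at(p0)$energy
  ## L-BFGS with the analytic gradient; positions may drift outside the
  ## primary cell during the search (minimum image keeps energies right)
  ## and are wrapped afterwards
  fit <- optim(p0, fn = function(p) eval_at(p)$energy,
               gr = function(p) as.numeric(eval_at(p)$gradient),
               method = "L-BFGS-B",
               control = list(maxit = max_iter, factr = 1e4))
  best <- if (fit$value <= e0) fit$par else p0
  res <- eval_at(best)
  if (max(abs(res$gradient)) > force_tol && fit$value <= e0) {
    fit2 <- optim(best, fn = function(p) eval_at(p)$energy,
                  gr = function(p) as.numeric(eval_at(p)$gradient),
                  method = "L-BFGS-B",
                  control = list(maxit = max_iter, factr = 1e4))
    if (fit2$value <= res$energy) {
      best <- fit2$par
      res <- eval_at(best)
    }
  }
  box$positions <- matrix(best, n, 3) %% box$edge
  attr(box, "energy_before") <- e0
  attr(box, "energy_after") <- res$energy
  box
}

## flatten per-atom parameters and build intramolecular distance restraints
## (bonds plus 1-3 pairs, k = 300 kcal/mol/A^2) from the input geometries
box_system <- function(box, restraint_k = 300) {
  sigma <- box_atom_field(box, "sigma")
  epsilon <- box_atom_field(box, "epsilon")
  charges <- box_atom_field(box, "charges")
  masses <- box_atom_field(box, "masses")
  if (anyNA(charges) || anyNA(sigma))
    stop("all molecules in the box must be parameterized")
  offsets <- cumsum(c(0, vapply(box$molecules, n_atoms, 1L)))
  restraints <- list()
  for (m in seq_along(box$molecules)) {
    mol <- box$molecules[[m]]
    pairs <- restraint_pairs(mol)
    if (nrow(pairs)) {
      rows <- box$molecule_index == m
      pos <- box$positions[rows, , drop = FALSE]
      ## minimum-image reference distances: placed molecules may be
      ## wrapped across the periodic boundary
      dd <- pos[pairs[, 1], , drop = FALSE] -
        pos[pairs[, 2], , drop = FALSE]
      dd <- dd - box$edge * round(dd / box$edge)
      r0 <- sqrt(rowSums(dd^2))
      restraints[[m]] <- cbind(pairs + offsets[m], r0, restraint_k)
    }
  }
  restraints <- if (length(restraints)) do.call(rbind, restraints) else
    matrix(numeric(), ncol = 4)
  list(molecule_index = as.integer(box$molecule_index), sigma = sigma,
       epsilon = epsilon, charges = charges, masses = masses,
       restraints = restraints)
}

## bonds plus bonded second neighbors (angle-defining 1-3 pairs)
restraint_pairs <- function(mol) {
  b <- mol$bonds
  if (!nrow(b)) return(matrix(integer(), ncol = 2))
  adj <- lapply(seq_len(n_atoms(mol)), function(i)
    sort(c(b[b[, 1] == i, 2], b[b[, 2] == i, 1])))
  one_three <- list()
  for (j in seq_along(adj)) {
    nb <- adj[[j]]
    if (length(nb) >= 2) {
      cmb <- t(combn(nb, 2))
      one_three[[j]] <- cmb
    }
  }
  pairs <- rbind(b, do.call(rbind, one_three))
  canonical_bonds(pairs)
}

#' Run molecular dynamics on a simulation box
#'
#' Velocity-Verlet integration with minimum-image periodic boundaries and a
#' non-bonded cutoff. Intermolecular interactions are Lennard-Jones plus
#' Coulomb from the molecules' assigned parameters; intramolecular geometry
#' is held near the input conformer by stiff harmonic bond and 1-3 distance
#' restraints. An Andersen thermostat redraws atom velocities from the
#' Maxwell-Boltzmann distribution at the configured collision rate. Frames
#' are recorded every `record_interval` steps after equilibration.
#'
#' @param box a `simulation_box` of parameterized molecules.
#' @param settings an [md_settings()] object.
#' @param model `energy_model` (Coulomb constant and dielectric for the
#'   intermolecular terms).
#' @param seed optional RNG seed (velocities, thermostat).
#' @param record_positions store frames (default `TRUE`); disable to keep
#'   only the energy series.
#' @return An `md_trajectory`: list with `frames` (n x 3 matrices),
#'   `steps`, `potential`, `kinetic`, `molecule_index`, `edge`,
#'   `solute_index` and final positions/velocities.
#' @export
run_md <- function(box, settings = md_settings(), model = energy_model(),
                   seed = NULL, record_positions = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  sys <- box_system(box)
  n <- nrow(box$positions)
  kT <- boltzmann_constant() * settings$temperature
  sd_v <- sqrt(kT * .ACCEL_CONV / sys$masses)
  vel <- matrix(rnorm(3 * n), n, 3) * sd_v
  nu <- settings$thermostat_rate / 1000 # ps^-1 -> fs^-1
  res <- cpp_run_md(box$positions, vel, sys$masses, sys$molecule_index,
                    sys$sigma, sys$epsilon, sys$charges, sys$restraints,
                    box$edge, settings$cutoff, settings$timestep,
                    settings$equilibration_steps, settings$production_steps,
                    settings$record_interval, nu, settings$temperature,
                    model$coulomb_constant, model$dielectric, TRUE,
                    record_positions)
  structure(list(frames = res$frames, steps = res$steps,
                 potential = res$potential, kinetic = res$kinetic,
                 molecule_index = sys$molecule_index, edge = box$edge,
                 elements = box_atom_field(box, "elements"),
                 solute_index = box$solute_index,
                 final_positions = res$final_positions,
                 final_velocities = res$final_velocities,
                 settings = settings),
            class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf("<md_trajectory> %d recorded frames, %d atoms, edge %.3f A\n",
              length(x$frames), length(x$molecule_index), x$edge))
  invisible(x)
}

#' Kinetic temperature series of a trajectory
#' @param traj an `md_trajectory`.
#' @return Temperatures (K) at the recorded steps.
#' @export
kinetic_temperature <- function(traj) {
  n <- length(traj$molecule_index)
  2 * traj$kinetic / (3 * n * boltzmann_constant())
}

#' Molecular neighbor criterion
#'
#' Two molecules are neighbors when any atom of one lies within the sum of
#' the two atoms' van der Waals radii plus a catch radius of any atom of
#' the other ("less than or equal to"). Radii default to the Bondi table.
#'
#' @param catch_radius extra distance in Angstrom (default 1).
#' @param radii named per-element radius table (Angstrom).
#' @return A `neighbor_criterion`.
#' @export
neighbor_criterion <- function(catch_radius = 1, radii = NULL) {
  stopifnot(catch_radius >= 0)
  structure(list(catch_radius = catch_radius, radii = radii),
            class = "neighbor_criterion")
}

atom_radii <- function(traj_or_box, criterion) {
  mols <- traj_or_box$molecules
  elements <- if (!is.null(mols))
    unlist(lapply(mols, `[[`, "elements"), use.names = FALSE)
  else traj_or_box$elements
  if (is.null(criterion$radii)) bondi_radii(elements)
  else unname(criterion$radii[normalize_elements(elements)])
}

#' Count neighbor molecules by brute force
#'
#' Distances between every solute atom and every solvent atom (minimum
#' image); a solvent molecule is counted once if any atom pair is within
#' the criterion threshold.
#'
#' @param positions n x 3 atom positions (Angstrom).
#' @param molecule_index per-atom owning-molecule id.
#' @param solute_index molecule id of the solute.
#' @param elements per-atom element symbols (for the vdW radii).
#' @param criterion a [neighbor_criterion()].
#' @param edge cubic box edge (Angstrom).
#' @return Integer neighbor count.
#' @export
count_neighbors_bruteforce <- function(positions, molecule_index,
                                       solute_index, elements,
                                       criterion = neighbor_criterion(),
                                       edge) {
  radii <- if (is.null(criterion$radii)) bondi_radii(elements)
           else unname(criterion$radii[normalize_elements(elements)])
  cpp_count_neighbors_brute(as.matrix(positions),
                            as.integer(molecule_index),
                            as.integer(solute_index), radii,
                            criterion$catch_radius, edge, TRUE)
}

#' Count neighbor molecules with the cell-index method
#'
#' Identical result to [count_neighbors_bruteforce()] but only distances to
#' atoms in the 27 neighboring cells are considered; cells are sized at
#' least as large as the maximum threshold distance. Boxes shorter than
#' three cells fall back to brute force with a notice.
#'
#' @inheritParams count_neighbors_bruteforce
#' @return Integer neighbor count.
#' @export
count_neighbors_cellindex <- function(positions, molecule_index,
                                      solute_index, elements,
                                      criterion = neighbor_criterion(),
                                      edge) {
  radii <- if (is.null(criterion$radii)) bondi_radii(elements)
           else unname(criterion$radii[normalize_elements(elements)])
  max_thr <- 2 * max(radii) + criterion$catch_radius
  ncell <- floor(edge / max_thr)
  if (ncell < 3) {
    message("box shorter than 3 cells; falling back to brute force")
    return(cpp_count_neighbors_brute(as.matrix(positions),
                                     as.integer(molecule_index),
                                     as.integer(solute_index), radii,
                                     criterion$catch_radius, edge, TRUE))
  }
  cpp_count_neighbors_cell(as.matrix(positions),
                           as.integer(molecule_index),
                           as.integer(solute_index), radii,
                           criterion$catch_radius, edge, as.integer(ncell))
}

#' Estimate a coordination number from a trajectory
#'
#' Counts the solvent molecules neighboring the solute in every recorded
#' frame and averages the counts; the running mean gives the convergence
#' series of the coordination number Z_ij.
#'
#' @param traj an `md_trajectory` with a solute, or a list with `frames`,
#'   `molecule_index`, `elements`, `edge`, `solute_index`.
#' @param criterion a [neighbor_criterion()].
#' @param method `"cellindex"` (default) or `"bruteforce"`.
#' @return A `coordination_estimate`: `per_frame_counts`, `running_mean`
#'   series, and the final estimate `z`.
#' @export
estimate_coordination_number <- function(traj,
                                         criterion = neighbor_criterion(),
                                         method = c("cellindex",
                                                    "bruteforce")) {
  method <- match.arg(method)
  if (!length(traj$frames)) stop("trajectory has no recorded frames")
  if (is.na(traj$solute_index %||% NA)) stop("trajectory has no solute")
  elements <- traj$elements %||%
    unlist(lapply(traj$molecules, `[[`, "elements"), use.names = FALSE)
  counter <- switch(method, cellindex = count_neighbors_cellindex,
                    bruteforce = count_neighbors_bruteforce)
  counts <- vapply(traj$frames, function(f)
    counter(f, traj$molecule_index, traj$solute_index, elements,
            criterion, traj$edge), 1L)
  structure(list(per_frame_counts = counts,
                 running_mean = cumsum(counts) / seq_along(counts),
                 n_frames = length(counts), z = mean(counts)),
            class = "coordination_estimate")
}

#' @export
print.coordination_estimate <- function(x, ...) {
  cat(sprintf("<coordination_estimate> Z = %.3f over %d frames\n",
              x$z, x$n_frames))
  invisible(x)
}
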