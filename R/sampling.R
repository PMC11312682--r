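#' Fibonacci sphere lattice
#'
#' Near-uniform unit-sphere points from the golden-angle spiral: the k-th
#' point (k = 0, ..., n-1) has z = 1 - (2k+1)/n and azimuth
#' k * 2*pi*(1 - 1/phi) with phi the golden ratio. Compared with a
#' latitude-longitude grid the points are more evenly spaced with smaller
#' axial anisotropy, which is why the configuration sampling uses them.
#'
#' @param n number of points (>= 1).
#' @return An n x 3 matrix of unit vectors, class `sphere_lattice`.
#' @export
fibonacci_sphere <- function(n) {
  if (n < 1) stop("n must be >= 1")
  k <- seq_len(n) - 1
  z <- 1 - (2 * k + 1) / n
  phi <- (1 + sqrt(5)) / 2
  azimuth <- k * 2 * pi * (1 - 1 / phi)
  s <- sqrt(pmax(1 - z^2, 0))
  pts <- cbind(s * cos(azimuth), s * sin(azimuth), z)
  structure(pts, class = c("sphere_lattice", "matrix", "array"))
}

#' Minimal rotation taking a lattice point onto the scan axis
#'
#' Returns the 3 x 3 rotation about the axis perpendicular to both vectors
#' that maps `point` onto `sign * axis`. The degenerate antiparallel case is
#' handled by a 180-degree rotation about a fixed fallback axis
#' perpendicular to the target, so results are deterministic.
#'
#' @param point unit 3-vector (a sphere lattice point).
#' @param axis unit target axis (default +x, the center-center axis).
#' @param sign +1 or -1: map onto `axis` or `-axis`.
#' @return A 3 x 3 rotation matrix.
#' @export
orient_to_axis <- function(point, axis = c(1, 0, 0), sign = 1) {
  p <- point / sqrt(sum(point^2))
  t <- sign * axis / sqrt(sum(axis^2))
  cth <- sum(p * t)
  if (cth < -1 + 1e-12) {
    a <- if (abs(t[1]) > 0.9) c(0, 1, 0) else c(1, 0, 0)
    a <- a - sum(a * t) * t
    a <- a / sqrt(sum(a^2))
    return(2 * tcrossprod(a) - diag(3))
  }
  v <- c(p[2] * t[3] - p[3] * t[2],
         p[3] * t[1] - p[1] * t[3],
         p[1] * t[2] - p[2] * t[1])
  K <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + K + K %*% K / (1 + cth)
}

#' Rotation about an axis
#' @param axis rotation axis (any nonzero 3-vector).
#' @param angle rotation angle in radians.
#' @return A 3 x 3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
}

#' Enumerate rigid dimer configurations at a fixed center distance
#'
#' Generates all `n_sphere^2 * n_rot` relative placements of two rigid
#' monomers at center separation `r_fix`: both molecules are rotated so that
#' one lattice point each and both centers lie on a straight axis, and the
#' second molecule is additionally spun about that axis in `n_rot` equal
#' steps (only molecule j is spun). With `evaluate = TRUE` the interaction
#' energy of every configuration is computed in compiled batch code.
#'
#' @param mol_i,mol_j rigid monomers.
#' @param r_fix center-center distance (Angstrom), > 0.
#' @param n_sphere lattice points per sphere (default 144).
#' @param n_rot axial spin steps for molecule j (default 16).
#' @param params `pair_params` for the dimer; defaults to
#'   [pair_params()] with `model`.
#' @param model energy model used when `params` is not given.
#' @param center `"geometric"` or `"mass"` center convention.
#' @param evaluate compute energies (default `TRUE`); otherwise only the
#'   configuration index set is set up.
#' @return A `config_set`: list with `energies` (length
#'   `n_sphere^2 * n_rot`, or `NULL`), lattice, counts, and the centered
#'   monomer coordinates needed to rebuild any configuration.
#' @export
enumerate_configurations <- function(mol_i, mol_j, r_fix, n_sphere = 144,
                                     n_rot = 16, params = NULL,
                                     model = energy_model(),
                                     center = c("geometric", "mass"),
                                     evaluate = TRUE) {
  if (r_fix <= 0) stop("r_fix must be positive")
  center <- match.arg(center)
  lattice <- fibonacci_sphere(n_sphere)
  xi <- centered_coords(mol_i, center)
  xj <- centered_coords(mol_j, center)
  energies <- NULL
  if (evaluate) {
    if (is.null(params)) params <- pair_params(mol_i, mol_j, model)
    energies <- cpp_enumerate_energies(
      xi, xj, unclass(lattice), as.integer(n_rot), r_fix,
      params$r_mat, params$eps_mat, params$qq_mat,
      vdw_form_code(params$model), elec_buffered(params$model))
  }
  structure(list(energies = energies, lattice = lattice,
                 n_sphere = as.integer(n_sphere),
                 n_rot = as.integer(n_rot), r_fix = r_fix,
                 xi = xi, xj = xj, center = center),
            class = "config_set")
}

vdw_form_code <- function(model) {
  if (model$vdw_form == "lj-12-6") 0L else 1L
}
elec_buffered <- function(model) {
  model$electrostatics == "buffered-coulomb"
}

#' @export
print.config_set <- function(x, ...) {
  cat(sprintf(
    "<config_set> %d x %d x %d = %d configurations at r = %.3f A\n",
    x$n_sphere, x$n_sphere, x$n_rot, configuration_count(x), x$r_fix))
  if (!is.null(x$energies))
    cat(sprintf("  E range [%.4f, %.4f] kcal/mol\n",
                min(x$energies), max(x$energies)))
  invisible(x)
}

#' Number of configurations in a configuration set
#' @param configs a `config_set`.
#' @export
configuration_count <- function(configs) {
  as.integer(configs$n_sphere) * as.integer(configs$n_sphere) *
    as.integer(configs$n_rot)
}

## flat index -> (point_i, point_j, spin), all 1-based;
## idx = ((a-1)*Ns + (b-1))*Nrot + k
decode_config <- function(configs, idx) {
  nr <- configs$n_rot
  ns <- configs$n_sphere
  k <- (idx - 1L) %% nr + 1L
  ab <- (idx - 1L) %/% nr
  b <- ab %% ns + 1L
  a <- ab %/% ns + 1L
  c(point_i = a, point_j = b, spin = k)
}

#' Rebuild the dimer coordinates of one sampled configuration
#'
#' @param configs a `config_set`.
#' @param index flat configuration index (1-based; ties in energy are broken
#'   toward the lowest index, i.e. lexicographically smallest
#'   (point_i, point_j, spin)).
#' @return List with `coords_i`, `coords_j` (molecule i centered at the
#'   origin, molecule j at distance r on the +x axis) and the decoded
#'   indices.
#' @export
dimer_coordinates <- function(configs, index) {
  dec <- decode_config(configs, index)
  Ri <- orient_to_axis(configs$lattice[dec[["point_i"]], ], sign = 1)
  Rj <- orient_to_axis(configs$lattice[dec[["point_j"]], ], sign = -1)
  spin <- rotation_about_axis(c(1, 0, 0),
                              2 * pi * (dec[["spin"]] - 1L) / configs$n_rot)
  ci <- configs$xi %*% t(Ri)
  cj <- configs$xj %*% t(Rj) %*% t(spin)
  cj[, 1] <- cj[, 1] + configs$r_fix
  list(coords_i = ci, coords_j = cj, point_i = dec[["point_i"]],
       point_j = dec[["point_j"]], spin = dec[["spin"]])
}

#' Boltzmann-weighted average energy
#'
#' Sum(E w) / Sum(w) with w = exp(-(E - reference)/kB T). The result is
#' independent of the reference energy (the shift cancels); for numerical
#' stability the batch minimum is subtracted by default.
#'
#' @param energies numeric vector of configuration energies (kcal/mol).
#' @param temperature temperature in K (> 0).
#' @param reference_energy reference subtracted inside the exponent.
#' @return Weighted mean energy (kcal/mol).
#' @export
boltzmann_average <- function(energies, temperature,
                              reference_energy = min(energies)) {
  if (!length(energies)) stop("no energies to average")
  if (temperature <= 0) stop("temperature must be positive")
  x <- -(energies - min(energies)) / (boltzmann_constant() * temperature)
  w <- exp(x)
  sum(energies * w) / sum(w)
}

#' Scan the dimer interaction over a distance grid
#'
#' For every center distance on the grid, enumerates all
#' `n_sphere^2 * n_rot` rigid configurations, records the minimum sampled
#' energy E^C* and the Boltzmann-averaged energy <E>, and keeps the indices
#' of the minimum configuration C*.
#'
#' @inheritParams enumerate_configurations
#' @param r_start,r_end,r_step distance grid in Angstrom (defaults 3 to 16
#'   by 0.5, endpoints included).
#' @param temperature averaging temperature (K), default 298.
#' @return A `distance_scan`: data.frame-backed object with one row per
#'   distance (`distance`, `e_cstar`, `e_mean`, `point_i`, `point_j`,
#'   `spin`).
#' @export
scan_distance_grid <- function(mol_i, mol_j, r_start = 3, r_end = 16,
                               r_step = 0.5, n_sphere = 144, n_rot = 16,
                               temperature = 298, params = NULL,
                               model = energy_model(),
                               center = c("geometric", "mass")) {
  if (r_start > r_end) stop("r_start must not exceed r_end")
  center <- match.arg(center)
  grid <- seq(r_start, r_end, by = r_step)
  if (!length(grid)) stop("empty distance grid")
  if (is.null(params)) params <- pair_params(mol_i, mol_j, model)
  rows <- lapply(grid, function(r) {
    cfg <- enumerate_configurations(mol_i, mol_j, r, n_sphere, n_rot,
                                    params = params, center = center)
    best <- which.min(cfg$energies)
    dec <- decode_config(cfg, best)
    data.frame(distance = r, e_cstar = cfg$energies[best],
               e_mean = boltzmann_average(cfg$energies, temperature),
               point_i = dec[["point_i"]], point_j = dec[["point_j"]],
               spin = dec[["spin"]])
  })
  res <- do.call(rbind, rows)
  structure(res, class = c("distance_scan", "data.frame"),
            n_sphere = as.integer(n_sphere), n_rot = as.integer(n_rot),
            temperature = temperature, center = center)
}

#' Refine the distance of the sampled minimum
#'
#' Multi-resolution refinement of a coarse distance scan: re-scans a
#' +/- 0.5 A window around the incumbent minimum at 0.1 A resolution, then
#' a +/- 0.1 A window around that minimum at 0.01 A, and returns the
#' best (finest) configuration C*. Ties go to the first (smallest) grid
#' distance.
#'
#' @param scan a `distance_scan` from [scan_distance_grid()].
#' @param mol_i,mol_j the monomers used for the scan.
#' @param params,model,center as in [scan_distance_grid()]; pass the same
#'   values that produced `scan`.
#' @param windows,steps refinement window half-widths and step sizes
#'   (defaults 0.5/0.1 then 0.1/0.01).
#' @return List with `best` (single-row `distance_scan` at the finest
#'   resolution), `history` (list of refinement scans) and `r_min`.
#' @export
refine_minimum <- function(scan, mol_i, mol_j, params = NULL,
                           model = energy_model(),
                           center = attr(scan, "center") %||% "geometric",
                           windows = c(0.5, 0.1), steps = c(0.1, 0.01)) {
  stopifnot(nrow(scan) >= 1, length(windows) == length(steps))
  if (is.null(params)) params <- pair_params(mol_i, mol_j, model)
  n_sphere <- attr(scan, "n_sphere")
  n_rot <- attr(scan, "n_rot")
  temperature <- attr(scan, "temperature") %||% 298
  incumbent <- scan[which.min(scan$e_cstar), , drop = FALSE]
  history <- list(coarse = scan)
  for (lvl in seq_along(windows)) {
    lo <- max(incumbent$distance - windows[lvl], steps[lvl])
    hi <- incumbent$distance + windows[lvl]
    sub <- scan_distance_grid(mol_i, mol_j, lo, hi, steps[lvl],
                              n_sphere, n_rot, temperature,
                              params = params, center = center)
    history[[paste0("step_", steps[lvl])]] <- sub
    cand <- sub[which.min(sub$e_cstar), , drop = FALSE]
    ## the refined window contains the incumbent, so this cannot go up
    incumbent <- cand
  }
  list(best = incumbent, history = history, r_min = incumbent$distance)
}

#' Extract the interaction curves from a distance scan
#'
#' @param scan a `distance_scan`.
#' @param path optional CSV output path.
#' @return data.frame with columns `r`, `e_cstar`, `e_mean` sorted by
#'   distance.
#' @export
extract_curves <- function(scan, path = NULL) {
  out <- data.frame(r = scan$distance, e_cstar = scan$e_cstar,
                    e_mean = scan$e_mean)
  out <- out[order(out$r), ]
  rownames(out) <- NULL
  if (!is.null(path)) write.csv(out, path, row.names = FALSE)
  out
}

#' Optimize a dimer starting from a sampled configuration
#'
#' Local optimization of the near-minimum dimer configuration C*. Two
#' backends satisfy the optimizer contract: `"rigid"` keeps both monomers
#' internally frozen and minimizes the interaction energy over the 6
#' relative rigid-body degrees of freedom of molecule j; `"mmff94"` performs
#' an unconstrained all-atom MMFF94 minimization (the monomers are no longer
#' confined to their input conformers). In both cases the reported `e_min`
#' is the intermolecular (non-bonded pair) energy at the optimized geometry
#' and `r_min` the center separation there.
#'
#' @param mol_i,mol_j the monomers.
#' @param coords_i,coords_j starting dimer coordinates (e.g. from
#'   [dimer_coordinates()] at the refined C*).
#' @param backend `"rigid"` or `"mmff94"`.
#' @param params `pair_params` used for the interaction energy (required
#'   for `"rigid"`; for `"mmff94"` it defaults to [mmff94_pair_params()]).
#' @param center center convention for `r_min`.
#' @param maxit iteration budget for the rigid-body optimizer.
#' @return An `optimized_dimer`: list with `coords_i`, `coords_j`, `e_min`
#'   (kcal/mol), `r_min` (Angstrom) and the backend identity.
#' @export
optimize_dimer <- function(mol_i, mol_j, coords_i, coords_j,
                           backend = c("rigid", "mmff94"), params = NULL,
                           center = c("geometric", "mass"), maxit = 2000) {
  backend <- match.arg(backend)
  center <- match.arg(center)
  coords_i <- as.matrix(coords_i)
  coords_j <- as.matrix(coords_j)
  if (backend == "rigid") {
    if (is.null(params)) stop("rigid backend needs pair_params")
    cj0 <- coords_j
    ctr0 <- colMeans(cj0)
    cj_local <- cj0 - matrix(ctr0, nrow(cj0), 3, byrow = TRUE)
    vdw_code <- vdw_form_code(params$model)
    buf <- elec_buffered(params$model)
    objective <- function(p) {
      rot <- rotation_vector_matrix(p[1:3])
      cj <- cj_local %*% t(rot) +
        matrix(ctr0 + p[4:6], nrow(cj0), 3, byrow = TRUE)
      cpp_config_energy(coords_i, cj, params$r_mat, params$eps_mat,
                        params$qq_mat, vdw_code, buf)[1]
    }
    fit <- optim(rep(0, 6), objective, method = "Nelder-Mead",
                 control = list(maxit = maxit, reltol = 1e-12))
    ## polish with a restart (Nelder-Mead benefits from one)
    fit <- optim(fit$par, objective, method = "Nelder-Mead",
                 control = list(maxit = maxit, reltol = 1e-14))
    rot <- rotation_vector_matrix(fit$par[1:3])
    coords_j_new <- cj_local %*% t(rot) +
      matrix(ctr0 + fit$par[4:6], nrow(cj0), 3, byrow = TRUE)
    coords_i_new <- coords_i
    e_min <- fit$value
  } else {
    min_res <- mmff94_minimize(list(mol_i, mol_j),
                               coords = list(coords_i, coords_j))
    coords_i_new <- min_res$coords[[1]]
    coords_j_new <- min_res$coords[[2]]
    if (is.null(params)) params <- mmff94_pair_params(mol_i, mol_j)
    e_min <- pair_interaction_energy(coords_i_new, coords_j_new,
                                     params)$total
  }
  ctr_method <- if (center == "geometric") "geometric" else "mass"
  mi <- mol_i; coords(mi) <- coords_i_new
  mj <- mol_j; coords(mj) <- coords_j_new
  r_min <- sqrt(sum((molecule_center(mj, ctr_method) -
                     molecule_center(mi, ctr_method))^2))
  structure(list(coords_i = coords_i_new, coords_j = coords_j_new,
                 e_min = e_min, r_min = r_min, backend = backend),
            class = "optimized_dimer")
}

#' @export
print.optimized_dimer <- function(x, ...) {
  cat(sprintf("<optimized_dimer> backend %s: E_min %.4f kcal/mol at r = %.3f A\n",
              x$backend, x$e_min, x$r_min))
  invisible(x)
}

## rotation from a rotation vector (axis * angle)
rotation_vector_matrix <- function(v) {
  th <- sqrt(sum(v^2))
  if (th < 1e-12) return(diag(3))
  rotation_about_axis(v / th, th)
}
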