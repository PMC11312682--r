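#' Differential pair interaction energy
#'
#' Excess of the i-j interaction over the mean of the two self
#' interactions: e_ij - (e_ii + e_jj)/2. Applies identically to global
#' minimum energies and to Boltzmann-averaged minima.
#'
#' @param e_ii,e_jj,e_ij interaction energies (kcal/mol).
#' @return Differential energy (kcal/mol); zero for self pairs.
#' @export
differential_energy <- function(e_ii, e_jj, e_ij) {
  stopifnot(is.finite(e_ii), is.finite(e_jj), is.finite(e_ij))
  e_ij - (e_ii + e_jj) / 2
}

#' Coordination-weighted differential pair interaction energy
#'
#' (Z_ij E_ij + Z_ji E_ji)/2 - (Z_ii E_ii + Z_jj E_jj)/2. The energy matrix
#' is symmetric (E_ij = E_ji) but the coordination numbers generally are
#' not (Z_ij != Z_ji). With all Z equal to 1 this reduces to
#' [differential_energy()].
#'
#' @param e symmetric energy matrix with dimnames (kcal/mol).
#' @param z coordination-number matrix with the same labels.
#' @param i,j labels (or indices) of the two molecules.
#' @return Differential energy (kcal/mol).
#' @export
differential_energy_z <- function(e, z, i, j) {
  for (lab in list(i, j)) {
    if (is.character(lab) &&
        (!lab %in% rownames(e) || !lab %in% rownames(z)))
      stop("no entry for '", lab, "' in the energy/coordination matrices")
  }
  (z[i, j] * e[i, j] + z[j, i] * e[j, i]) / 2 -
    (z[i, i] * e[i, i] + z[j, j] * e[j, j]) / 2
}

#' Flory-Huggins interaction parameter
#'
#' chi_ij = Delta E^Z / (kB T): the coordination-weighted differential pair
#' interaction energy in units of the thermal energy.
#'
#' @param delta_e_z differential pair energy (kcal/mol).
#' @param temperature temperature (K), > 0.
#' @return Dimensionless chi.
#' @export
flory_huggins <- function(delta_e_z, temperature = 298) {
  stopifnot(temperature > 0)
  delta_e_z / (boltzmann_constant() * temperature)
}

#' Conversion coefficient between chi and the DPD repulsion increment
#'
#' The linear chi -> a_ij mapping uses the coefficient 3.4965, the inverse
#' of the 0.286 proportionality between chi and the excess repulsion at
#' DPD density 3.
#'
#' @param digits rounding applied to the reciprocal (4 by convention; use
#'   `Inf` for full precision 1/0.286).
#' @return The coefficient.
#' @export
conversion_coefficient <- function(digits = 4) {
  if (is.infinite(digits)) 1 / 0.286 else round(1 / 0.286, digits)
}

#' DPD repulsion parameter from a Flory-Huggins parameter
#'
#' a_ij(T) = 75 kB T / rho_DPD + 3.4965 kB T chi_ij, with the thermal
#' energy expressed in units where kB * reference_temperature = 1 (default
#' reference 300 K), i.e. a_ij = (T/T_ref) (75/rho + 3.4965 chi). At
#' chi = 0, rho = 3 and T = 298 K this gives the diagonal value 24.83.
#'
#' @param chi Flory-Huggins parameter (may be a vector or matrix).
#' @param rho_dpd dimensionless DPD density (> 0), default 3.
#' @param temperature thermodynamic temperature (K).
#' @param reference_temperature temperature at which kB T is unity (K).
#' @return Repulsion in kB T units (same shape as `chi`).
#' @export
dpd_repulsion <- function(chi, rho_dpd = 3, temperature = 298,
                          reference_temperature = 300) {
  stopifnot(rho_dpd > 0, temperature > 0, reference_temperature > 0)
  (temperature / reference_temperature) *
    (75 / rho_dpd + conversion_coefficient() * chi)
}

#' Linearly scale the off-diagonal repulsions of a particle set
#'
#' Rescales the off-diagonal a_ij about the diagonal value so that the
#' maximum absolute deviation between the smallest off-diagonal entry and
#' the diagonal a_ii is `max_deviation`:
#' a'_ij = a_ii + s (a_ij - a_ii) with
#' s = max_deviation / |min_offdiag - a_ii|. The diagonal is forced to
#' `diagonal_value`; the pair attaining the minimum becomes the scaling
#' base pair. The ranking of off-diagonal repulsions is preserved.
#'
#' @param raw_a symmetric repulsion matrix (kB T units) with dimnames.
#' @param diagonal_value common diagonal a_ii (default 24.83, the 298 K
#'   value).
#' @param max_deviation target deviation of the smallest a_ij from the
#'   diagonal (default 20).
#' @param rho_dpd,temperature metadata recorded with the set.
#' @return A `particle_set`: names, scaled matrix `a`, diagonal value and
#'   scaling record (factor, max deviation, base pair).
#' @export
scale_particle_set <- function(raw_a, diagonal_value = 24.83,
                               max_deviation = 20, rho_dpd = 3,
                               temperature = 298) {
  raw_a <- as.matrix(raw_a)
  if (nrow(raw_a) != ncol(raw_a)) stop("repulsion matrix must be square")
  if (max(abs(raw_a - t(raw_a))) > 1e-8)
    stop("repulsion matrix must be symmetric")
  if (nrow(raw_a) < 2) stop("need at least one off-diagonal entry")
  off <- raw_a
  diag(off) <- NA
  mn <- min(off, na.rm = TRUE)
  if (abs(mn - diagonal_value) < 1e-12)
    stop("all off-diagonal repulsions equal the diagonal; ",
         "scaling factor undefined")
  s <- max_deviation / abs(mn - diagonal_value)
  a <- diagonal_value + s * (raw_a - diagonal_value)
  diag(a) <- diagonal_value
  idx <- sort(which(off == mn, arr.ind = TRUE)[1, ])
  nm <- rownames(raw_a) %||% as.character(seq_len(nrow(raw_a)))
  base_pair <- paste(nm[idx[1]], nm[idx[2]], sep = "-")
  structure(list(names = nm, a = a, diagonal_value = diagonal_value,
                 scaling = list(factor = s, max_deviation = max_deviation,
                                base_pair = base_pair),
                 rho_dpd = rho_dpd, temperature = temperature),
            class = "particle_set")
}

#' @export
print.particle_set <- function(x, ...) {
  cat(sprintf(
    "<particle_set> %d particles, a_ii = %.2f, min a_ij = %.2f (%s)\n",
    length(x$names), x$diagonal_value, min(x$a), x$scaling$base_pair))
  invisible(x)
}

#' Conservative DPD force
#'
#' Soft repulsion a_ij (1 - r) along the unit separation vector for r < 1
#' (DPD reduced units) and exactly zero for r >= 1; continuous at the
#' cutoff.
#'
#' @param r_vector separation vector r_i - r_j (reduced units).
#' @param a_ij repulsion parameter (>= 0).
#' @return Force vector on particle i (kB T / r_c units).
#' @export
dpd_conservative_force <- function(r_vector, a_ij) {
  stopifnot(a_ij >= 0)
  r <- sqrt(sum(r_vector^2))
  if (r == 0) stop("zero separation: unit vector undefined")
  if (r >= 1) return(c(0, 0, 0))
  a_ij * (1 - r) * r_vector / r
}

#' Export a particle set as CSV + JSON metadata
#'
#' Writes `<prefix>_a.csv` (the symmetric repulsion matrix) and
#' `<prefix>_meta.json` (temperature, DPD density, scaling record including
#' the base pair, and optional source energy and coordination matrices).
#'
#' @param ps a `particle_set`.
#' @param prefix output path prefix.
#' @param extra named list merged into the metadata (e.g. source matrices).
#' @return The two paths, invisibly.
#' @export
export_particle_set <- function(ps, prefix, extra = list()) {
  csv <- paste0(prefix, "_a.csv")
  meta <- paste0(prefix, "_meta.json")
  df <- as.data.frame(ps$a)
  names(df) <- ps$names
  write.csv(cbind(particle = ps$names, df), csv, row.names = FALSE)
  payload <- c(list(
    names = ps$names, diagonal_value = ps$diagonal_value,
    scaling = ps$scaling, rho_dpd = ps$rho_dpd,
    temperature = ps$temperature,
    software = paste0("mesopair ",
                      as.character(utils::packageVersion("mesopair")))),
    extra)
  jsonlite::write_json(payload, meta, auto_unbox = TRUE, digits = NA)
  invisible(c(csv, meta))
}

#' Re-import an exported particle set
#'
#' @param prefix the prefix passed to [export_particle_set()].
#' @return A `particle_set`.
#' @export
read_particle_set <- function(prefix) {
  tab <- read.csv(paste0(prefix, "_a.csv"), check.names = FALSE)
  meta <- jsonlite::fromJSON(paste0(prefix, "_meta.json"))
  a <- as.matrix(tab[, -1, drop = FALSE])
  rownames(a) <- colnames(a) <- tab$particle
  structure(list(names = tab$particle, a = a,
                 diagonal_value = meta$diagonal_value,
                 scaling = meta$scaling, rho_dpd = meta$rho_dpd,
                 temperature = meta$temperature),
            class = "particle_set")
}

#' Build a scaled DPD particle set from energies and coordination numbers
#'
#' Full mesoscopic mapping: coordination-weighted differential pair
#' energies for every pair, Flory-Huggins parameters at the given
#' temperature, raw DPD repulsions, then the linear off-diagonal scaling.
#' With `zij_one = TRUE` all coordination numbers are fixed at 1 (the
#' variant based solely on the averaged minimum energies).
#'
#' @param e_min symmetric matrix of (averaged) minimum interaction
#'   energies (kcal/mol) with dimnames.
#' @param z coordination-number matrix (ignored when `zij_one`).
#' @param temperature temperature (K).
#' @param rho_dpd DPD density.
#' @param diagonal_value,max_deviation scaling targets
#'   (see [scale_particle_set()]).
#' @param zij_one force Z_ij = 1 for all pairs.
#' @return A `particle_set`; the unscaled matrix and the chi matrix are
#'   attached as attributes.
#' @export
build_particle_set <- function(e_min, z = NULL, temperature = 298,
                               rho_dpd = 3, diagonal_value = 24.83,
                               max_deviation = 20, zij_one = FALSE) {
  e_min <- as.matrix(e_min)
  nm <- rownames(e_min)
  if (is.null(nm)) stop("energy matrix needs dimnames")
  if (zij_one || is.null(z))
    z <- matrix(1, nrow(e_min), ncol(e_min), dimnames = dimnames(e_min))
  chi <- matrix(0, nrow(e_min), ncol(e_min), dimnames = dimnames(e_min))
  for (i in nm) for (j in nm)
    chi[i, j] <- flory_huggins(differential_energy_z(e_min, z, i, j),
                               temperature)
  raw <- dpd_repulsion(chi, rho_dpd, temperature)
  ps <- scale_particle_set(raw, diagonal_value, max_deviation, rho_dpd,
                           temperature)
  attr(ps, "raw_a") <- raw
  attr(ps, "chi") <- chi
  ps
}
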