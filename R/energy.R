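#' Specify a non-bonded intermolecular energy model
#'
#' The interaction energy of a rigid monomer pair is the sum over all
#' intermolecular atom pairs of a van der Waals term and a point-charge
#' electrostatic term. Two vdW forms are supported: the 12-6 Lennard-Jones
#' potential and the MMFF94 buffered 14-7 form; electrostatics are plain
#' Coulomb or the MMFF94 buffered variant with (r + 0.05) in the
#' denominator. Intramolecular terms are excluded throughout: for rigid
#' monomers they cancel exactly in dimer-minus-monomers differences.
#'
#' @param vdw_form `"lj-12-6"` or `"buffered-14-7"`.
#' @param electrostatics `"coulomb"` or `"buffered-coulomb"`.
#' @param combination_rule `"lorentz-berthelot"` (arithmetic sigma,
#'   geometric epsilon) or `"geometric"` (both geometric).
#' @param dielectric relative dielectric constant (> 0).
#' @param coulomb_constant conversion constant in kcal A / (mol e^2).
#' @return An object of class `energy_model`.
#' @export
energy_model <- function(vdw_form = c("lj-12-6", "buffered-14-7"),
                         electrostatics = c("coulomb", "buffered-coulomb"),
                         combination_rule = c("lorentz-berthelot",
                                              "geometric"),
                         dielectric = 1,
                         coulomb_constant = .COULOMB_GENERIC) {
  vdw_form <- match.arg(vdw_form)
  electrostatics <- match.arg(electrostatics)
  combination_rule <- match.arg(combination_rule)
  stopifnot(dielectric > 0, coulomb_constant > 0)
  structure(list(vdw_form = vdw_form, electrostatics = electrostatics,
                 combination_rule = combination_rule,
                 dielectric = dielectric,
                 coulomb_constant = coulomb_constant),
            class = "energy_model")
}

#' @export
print.energy_model <- function(x, ...) {
  cat(sprintf("<energy_model> vdW %s + %s (%s rules, D = %g)\n",
              x$vdw_form, x$electrostatics, x$combination_rule,
              x$dielectric))
  invisible(x)
}

#' Lennard-Jones 12-6 pair term
#'
#' E(r) = 4 eps \[ (sigma/r)^12 - (sigma/r)^6 \], kcal/mol.
#'
#' @param r interatomic distance (Angstrom), > 0. Vectorized.
#' @param sigma_ij zero-crossing distance (Angstrom).
#' @param epsilon_ij well depth (kcal/mol).
#' @export
lj_pair_term <- function(r, sigma_ij, epsilon_ij) {
  if (any(r <= 0)) stop("r must be positive")
  sr6 <- (sigma_ij / r)^6
  4 * epsilon_ij * (sr6^2 - sr6)
}

#' MMFF94 buffered 14-7 van der Waals pair term
#'
#' E(r) = eps (1.07 R*/(r + 0.07 R*))^7 (1.12 R*^7/(r^7 + 0.12 R*^7) - 2)
#' with the published buffering constants 0.07 and 0.12; the minimum is
#' -eps at r = R*.
#'
#' @param r interatomic distance (Angstrom), > 0. Vectorized.
#' @param r_min_ij minimum-energy distance R* (Angstrom).
#' @param epsilon_ij well depth (kcal/mol).
#' @export
buffered_14_7_term <- function(r, r_min_ij, epsilon_ij) {
  if (any(r <= 0)) stop("r must be positive")
  epsilon_ij * (1.07 * r_min_ij / (r + 0.07 * r_min_ij))^7 *
    (1.12 * r_min_ij^7 / (r^7 + 0.12 * r_min_ij^7) - 2)
}

#' Point-charge electrostatic pair term
#'
#' E(r) = C q_i q_j / (D r), or C q_i q_j / (D (r + 0.05)) for the MMFF94
#' buffered variant.
#'
#' @param r interatomic distance (Angstrom). Vectorized.
#' @param q_i,q_j partial charges (e).
#' @param dielectric relative dielectric constant.
#' @param buffered use the buffered (r + 0.05) denominator.
#' @param coulomb_constant conversion constant (kcal A / (mol e^2)).
#' @export
coulomb_term <- function(r, q_i, q_j, dielectric = 1, buffered = FALSE,
                         coulomb_constant = .COULOMB_GENERIC) {
  if (!buffered && any(r <= 0)) stop("r must be positive")
  denom <- if (buffered) r + 0.05 else r
  coulomb_constant * q_i * q_j / (dielectric * denom)
}

#' Pairwise non-bonded parameters for a dimer
#'
#' Combines the per-atom vdW parameters of two parameterized monomers into
#' the ni x nj pair matrices the energy kernels consume, applying the
#' model's combination rule, and precomputes the Coulomb prefactor matrix
#' C q_i q_j / D.
#'
#' @param mol_i,mol_j parameterized `molecule`s (see [assign_parameters()]).
#' @param model an [energy_model()].
#' @return An object of class `pair_params` with elements `r_mat` (sigma or
#'   R* pair matrix), `eps_mat`, `qq_mat` and the model.
#' @export
pair_params <- function(mol_i, mol_j, model = energy_model()) {
  for (m in list(mol_i, mol_j))
    if (!is_parameterized(m))
      stop("molecule '", m$name, "' lacks parameters; ",
           "run assign_parameters() first")
  r_mat <- switch(model$combination_rule,
    "lorentz-berthelot" = outer(mol_i$sigma, mol_j$sigma, function(a, b)
      (a + b) / 2),
    "geometric" = sqrt(outer(mol_i$sigma, mol_j$sigma)))
  if (model$vdw_form == "buffered-14-7")
    r_mat <- r_mat * 2^(1 / 6) # sigma -> r_min for the 14-7 minimum position
  eps_mat <- sqrt(outer(mol_i$epsilon, mol_j$epsilon))
  qq_mat <- model$coulomb_constant *
    outer(mol_i$charges, mol_j$charges) / model$dielectric
  new_pair_params(r_mat, eps_mat, qq_mat, model,
                  source = "combined per-atom parameters")
}

new_pair_params <- function(r_mat, eps_mat, qq_mat, model, source) {
  structure(list(r_mat = r_mat, eps_mat = eps_mat, qq_mat = qq_mat,
                 model = model, source = source),
            class = "pair_params")
}

#' Rigid-pair intermolecular interaction energy
#'
#' Sums the model's vdW and electrostatic terms over all intermolecular
#' atom pairs of one dimer configuration. This is the reference scalar
#' implementation; the configuration-sampling kernels evaluate the same sum
#' in compiled batch code and are tested against it.
#'
#' @param coords_i,coords_j n x 3 coordinate matrices of the two monomers
#'   (Angstrom).
#' @param params a `pair_params` object (from [pair_params()] or
#'   [mmff94_pair_params()]).
#' @return A list of class `pair_energy` with components `vdw`,
#'   `electrostatic` and `total` (kcal/mol).
#' @export
pair_interaction_energy <- function(coords_i, coords_j, params) {
  stopifnot(inherits(params, "pair_params"))
  d <- pairwise_distances(as.matrix(coords_i), as.matrix(coords_j))
  if (any(d == 0)) stop("coincident atoms between the two monomers")
  model <- params$model
  vdw <- switch(model$vdw_form,
    "lj-12-6" = lj_pair_term(d, params$r_mat, params$eps_mat),
    "buffered-14-7" = buffered_14_7_term(d, params$r_mat, params$eps_mat))
  denom <- if (model$electrostatics == "buffered-coulomb") d + 0.05 else d
  elec <- params$qq_mat / denom
  structure(list(vdw = sum(vdw), electrostatic = sum(elec),
                 total = sum(vdw) + sum(elec)), class = "pair_energy")
}

#' @export
print.pair_energy <- function(x, ...) {
  cat(sprintf("vdW %.4f + electrostatic %.4f = %.4f kcal/mol\n",
              x$vdw, x$electrostatic, x$total))
  invisible(x)
}

pairwise_distances <- function(a, b) {
  ## ni x nj Euclidean distance matrix
  d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}
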