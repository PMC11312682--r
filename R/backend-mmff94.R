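## MMFF94 backend. Typing, bond-charge-increment partial charges, pairwise
## buffered 14-7 vdW parameters (with MMFF94's own combination rules) and
## all-atom local minimization are delegated to an external MMFF94
## implementation (RDKit) through a small python helper shipped with the
## package. The backend contract is: molecule in -> per-atom parameters out,
## or coordinates in -> minimized coordinates + energy out.

mmff94_python <- function() {
  p <- Sys.getenv("MESOPAIR_PYTHON", "")
  if (nzchar(p)) return(p)
  for (cand in c("python", "python3")) {
    path <- Sys.which(cand)
    if (nzchar(path)) return(path)
  }
  stop("no python interpreter found for the MMFF94 backend")
}

run_mmff94_backend <- function(payload) {
  script <- system.file("python", "mmff94_backend.py",
                        package = "mesopair", mustWork = TRUE)
  req <- tempfile(fileext = ".json")
  on.exit(unlink(req))
  jsonlite::write_json(payload, req, auto_unbox = TRUE, digits = NA)
  out <- suppressWarnings(
    system2(mmff94_python(), c(shQuote(script), shQuote(req)),
            stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status") %||% 0L
  if (status != 0L)
    stop("MMFF94 backend failed: ", paste(out, collapse = "\n"))
  jsonlite::fromJSON(paste(out, collapse = ""), simplifyMatrix = TRUE)
}

#' Is the MMFF94 backend available?
#'
#' @return `TRUE` if the python/RDKit MMFF94 provider can be executed.
#' @export
mmff94_available <- function() {
  ok <- tryCatch(isTRUE(run_mmff94_backend(list(mode = "check"))$ok),
                 error = function(e) FALSE)
  ok
}

#' Assign MMFF94 charges and atom types to a molecule
#'
#' Perceives connectivity from the 3D geometry, types every atom with
#' MMFF94 and stores the MMFF94 bond-charge-increment partial charges and
#' numeric atom types. vdW interactions for MMFF94 are pairwise (the MMFF94
#' combination rules are applied by the backend), so per-atom sigma/epsilon
#' are left unset; use [mmff94_pair_params()] for dimer energetics.
#'
#' @param mol a `molecule`.
#' @return The molecule with charges, types and bonds set.
#' @export
mmff94_assign <- function(mol) {
  res <- run_mmff94_backend(list(
    mode = "assign", elements = mol$elements, coords = mol$coords))
  mol$charges <- as.numeric(res$charges)
  mol$types <- as.character(res$types)
  if (length(res$bonds))
    mol$bonds <- canonical_bonds(matrix(as.integer(res$bonds), ncol = 2L))
  attr(mol, "parameter_source") <- "MMFF94 (RDKit backend)"
  mol
}

#' MMFF94 pairwise parameters for a dimer
#'
#' Returns the intermolecular pair matrices of MMFF94 buffered 14-7 R* and
#' epsilon values (MMFF94 combination rules, as published) together with the
#' buffered-Coulomb prefactors for the MMFF94 charges, ready for
#' [pair_interaction_energy()] and the configuration-sampling kernels.
#'
#' @param mol_i,mol_j `molecule`s.
#' @return A `pair_params` object whose model is buffered 14-7 vdW plus
#'   buffered Coulomb with the MMFF94 electrostatic constant.
#' @export
mmff94_pair_params <- function(mol_i, mol_j) {
  res <- run_mmff94_backend(list(
    mode = "pair_params",
    elements_i = mol_i$elements, coords_i = mol_i$coords,
    elements_j = mol_j$elements, coords_j = mol_j$coords))
  model <- energy_model("buffered-14-7", "buffered-coulomb",
                        coulomb_constant = .COULOMB_MMFF94)
  qq <- .COULOMB_MMFF94 * outer(as.numeric(res$q_i), as.numeric(res$q_j))
  new_pair_params(matrix(as.numeric(res$rstar), n_atoms(mol_i)),
                  matrix(as.numeric(res$eps), n_atoms(mol_i)),
                  qq, model, source = "MMFF94 (RDKit backend)")
}

#' Local MMFF94 minimization
#'
#' All-atom local optimization of one molecule or of a dimer (two
#' fragments, inter-fragment interactions included) with the full MMFF94
#' force field.
#'
#' @param fragments list of `molecule`s (one for a monomer, two for a
#'   dimer); each may carry its own coordinates.
#' @param coords optional list of coordinate matrices overriding the
#'   fragment coordinates.
#' @param max_iter maximum number of minimizer iterations.
#' @return A list with `coords` (list of per-fragment coordinate matrices),
#'   `energy` (total MMFF94 energy, kcal/mol) and `converged`.
#' @export
mmff94_minimize <- function(fragments, coords = NULL, max_iter = 100000) {
  if (inherits(fragments, "molecule")) fragments <- list(fragments)
  if (is.null(coords)) coords <- lapply(fragments, function(m) m$coords)
  stopifnot(length(coords) == length(fragments))
  res <- run_mmff94_backend(list(
    mode = "minimize",
    elements = lapply(fragments, function(m) m$elements),
    coords = lapply(coords, function(x) as.matrix(x)),
    max_iter = max_iter))
  all_xyz <- matrix(as.numeric(res$coords), ncol = 3L)
  sizes <- vapply(fragments, n_atoms, 1L)
  splits <- rep(seq_along(sizes), sizes)
  list(coords = unname(lapply(split.data.frame(all_xyz, splits),
                              function(d) unname(as.matrix(d)))),
       energy = as.numeric(res$energy),
       converged = isTRUE(res$converged))
}

#' Total MMFF94 energy of one or more fragments
#'
#' @param fragments list of `molecule`s (inter-fragment terms included).
#' @param coords optional list of coordinate matrices.
#' @return Energy in kcal/mol.
#' @export
mmff94_energy <- function(fragments, coords = NULL) {
  if (inherits(fragments, "molecule")) fragments <- list(fragments)
  if (is.null(coords)) coords <- lapply(fragments, function(m) m$coords)
  res <- run_mmff94_backend(list(
    mode = "energy",
    elements = lapply(fragments, function(m) m$elements),
    coords = lapply(coords, function(x) as.matrix(x))))
  as.numeric(res$energy)
}
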