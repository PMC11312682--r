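#' Construct a molecule
#'
#' The central container of the package: an ordered set of atoms with
#' Cartesian coordinates (Angstrom), optional force-field atom type labels,
#' partial charges (e) and van der Waals parameters, plus a bond list.
#'
#' @param elements character vector of chemical symbols.
#' @param coords numeric matrix with one row per atom and columns x, y, z
#'   (Angstrom).
#' @param bonds two-column integer matrix of 1-based atom index pairs, or
#'   `NULL` for no bonds.
#' @param name molecule label.
#' @param types optional character vector of force-field atom type labels.
#' @param charges optional numeric vector of partial charges (e).
#' @param sigma,epsilon optional per-atom Lennard-Jones parameters
#'   (Angstrom, kcal/mol).
#' @return An object of class `molecule`.
#' @examples
#' m <- molecule(c("O", "H", "H"),
#'               rbind(c(0, 0, 0), c(0.96, 0, 0), c(-0.24, 0.93, 0)),
#'               bonds = rbind(c(1, 2), c(1, 3)), name = "water")
#' n_atoms(m)
#' @export
molecule <- function(elements, coords, bonds = NULL, name = "molecule",
                     types = NULL, charges = NULL, sigma = NULL,
                     epsilon = NULL) {
  coords <- as.matrix(coords)
  if (is.null(dim(coords)) || ncol(coords) != 3L)
    stop("'coords' must be an n x 3 matrix")
  n <- nrow(coords)
  if (n < 1L) stop("a molecule needs at least one atom")
  if (length(elements) != n)
    stop("'elements' and 'coords' disagree on the atom count")
  elements <- normalize_elements(elements)
  unknown <- setdiff(unique(elements), .known_elements())
  if (length(unknown))
    stop("unknown element(s): ", paste(unknown, collapse = ", "))
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  if (is.null(bonds)) {
    bonds <- matrix(integer(), ncol = 2L)
  } else {
    bonds <- matrix(as.integer(as.matrix(bonds)), ncol = 2L)
    if (nrow(bonds) && (min(bonds) < 1L || max(bonds) > n))
      stop("bond index out of range [1, ", n, "]")
    if (any(bonds[, 1L] == bonds[, 2L])) stop("self-bonds are not allowed")
    bonds <- canonical_bonds(bonds)
  }
  storage.mode(coords) <- "double"
  dimnames(coords) <- NULL
  structure(list(
    name = name,
    elements = elements,
    coords = coords,
    bonds = bonds,
    types = if (is.null(types)) rep(NA_character_, n) else as.character(types),
    charges = if (is.null(charges)) rep(NA_real_, n) else as.numeric(charges),
    sigma = if (is.null(sigma)) rep(NA_real_, n) else as.numeric(sigma),
    epsilon = if (is.null(epsilon)) rep(NA_real_, n) else as.numeric(epsilon),
    masses = unname(.ATOMIC_MASSES[elements]),
    provenance = NULL
  ), class = "molecule")
}

normalize_elements <- function(x) {
  x <- as.character(x)
  paste0(toupper(substr(x, 1L, 1L)), tolower(substr(x, 2L, nchar(x))))
}

## sorted, deduplicated (i < j) bond matrix
canonical_bonds <- function(bonds) {
  if (!nrow(bonds)) return(matrix(integer(), ncol = 2L))
  b <- cbind(pmin(bonds[, 1L], bonds[, 2L]), pmax(bonds[, 1L], bonds[, 2L]))
  b <- unique(b)
  b[order(b[, 1L], b[, 2L]), , drop = FALSE]
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("<molecule> %s: %d atoms (%s), %d bonds\n", x$name,
              n_atoms(x), paste(unique(x$elements), collapse = " "),
              nrow(x$bonds)))
  if (is_parameterized(x))
    cat(sprintf("  parameterized (%s); net charge %.4f e\n",
                attr(x, "parameter_source") %||% "unknown source",
                sum(x$charges)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Number of atoms in a molecule
#' @param mol a `molecule`.
#' @export
n_atoms <- function(mol) nrow(mol$coords)

#' Atom coordinates of a molecule
#' @param mol a `molecule`.
#' @return n x 3 numeric matrix (Angstrom).
#' @export
coords <- function(mol) mol$coords

#' Replace the coordinates of a molecule
#' @param mol a `molecule`.
#' @param value n x 3 coordinate matrix.
#' @export
`coords<-` <- function(mol, value) {
  value <- as.matrix(value)
  stopifnot(nrow(value) == n_atoms(mol), ncol(value) == 3L)
  mol$coords <- unname(value)
  mol
}

is_parameterized <- function(mol) {
  !anyNA(mol$charges) && !anyNA(mol$sigma) && !anyNA(mol$epsilon)
}

#' Center of a molecule
#'
#' Returns the unweighted geometric center (default) or the mass-weighted
#' center of the atom coordinates. The rigid-body sampling places molecule
#' centers on the scan axis, so this convention defines the meaning of the
#' center-center distance r.
#'
#' @param mol a `molecule`.
#' @param method `"geometric"` (mean of atom positions, the default) or
#'   `"mass"` (center of mass with standard atomic masses).
#' @return length-3 numeric vector (Angstrom).
#' @export
molecule_center <- function(mol, method = c("geometric", "mass")) {
  method <- match.arg(method)
  if (method == "geometric") {
    colMeans(mol$coords)
  } else {
    w <- mol$masses / sum(mol$masses)
    as.numeric(crossprod(mol$coords, w))
  }
}

#' Translate a molecule
#' @param mol a `molecule`.
#' @param shift length-3 translation vector (Angstrom).
#' @export
translate_molecule <- function(mol, shift) {
  mol$coords <- mol$coords + matrix(shift, n_atoms(mol), 3L, byrow = TRUE)
  mol
}

## center coordinates at the chosen molecular center
centered_coords <- function(mol, method = "geometric") {
  ctr <- molecule_center(mol, method)
  mol$coords - matrix(ctr, n_atoms(mol), 3L, byrow = TRUE)
}
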