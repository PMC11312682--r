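.FIXTURE_FILES <- c(
  H2O = "h2o", Me = "me", Et = "et", MeOH = "meoh", EtOH = "etoh",
  Me2O = "me2o", HAc = "hac"
)

#' Bundled fixture molecules
#'
#' Small-molecule geometries shipped with the package: water (H2O), methane
#' (Me), ethane (Et), methanol (MeOH), ethanol (EtOH), dimethyl ether (Me2O)
#' and acetic acid (HAc). Geometries are MMFF94 locally optimized monomer
#' conformers stored as Tinker-XYZ text; atoms carry generic type labels that
#' are resolved against the bundled Lennard-Jones/point-charge table so the
#' returned molecule is ready for the generic energy model.
#'
#' @param name one of `"H2O"`, `"Me"`, `"Et"`, `"MeOH"`, `"EtOH"`, `"Me2O"`,
#'   `"HAc"`.
#' @param parameterize assign the bundled generic parameters (default `TRUE`).
#' @return A `molecule`.
#' @examples
#' fixture("H2O")
#' @export
fixture <- function(name, parameterize = TRUE) {
  if (!name %in% names(.FIXTURE_FILES))
    stop("unknown fixture '", name, "'; available: ",
         paste(names(.FIXTURE_FILES), collapse = ", "))
  path <- system.file("extdata", paste0(.FIXTURE_FILES[[name]], ".txyz"),
                      package = "mesopair", mustWork = TRUE)
  mol <- read_tinker_xyz(path)
  mol$name <- name
  if (parameterize) mol <- assign_parameters(mol, backend = "table")
  mol
}

#' Names of the bundled fixture molecules
#' @export
fixture_names <- function() names(.FIXTURE_FILES)

#' Read a non-bonded parameter table
#'
#' Structured text with one row per atom type: `type sigma epsilon charge`
#' (Angstrom, kcal/mol, e). Lines starting with `#` are ignored.
#'
#' @param path file path; defaults to the bundled generic table.
#' @return A data.frame with columns type, sigma, epsilon, charge.
#' @export
read_parameter_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "generic_params.txt",
                        package = "mesopair", mustWork = TRUE)
  tab <- read.table(path, comment.char = "#", stringsAsFactors = FALSE,
                    col.names = c("type", "sigma", "epsilon", "charge"))
  if (anyDuplicated(tab$type)) stop("duplicate atom type in ", path)
  tab
}

#' Assign non-bonded parameters to a molecule
#'
#' Resolves per-atom partial charges and van der Waals parameters. The
#' `"table"` backend looks the molecule's atom type labels up in a parameter
#' table (by default the bundled generic table covering the fixture set); the
#' `"mmff94"` backend delegates typing and bond-charge-increment charges to
#' an MMFF94 implementation (see [mmff94_assign()]).
#'
#' @param mol a `molecule`.
#' @param backend `"table"` or `"mmff94"`.
#' @param table parameter table for the table backend
#'   (see [read_parameter_table()]).
#' @return The molecule with charges and vdW parameters set; the parameter
#'   source is recorded in the `parameter_source` attribute.
#' @export
assign_parameters <- function(mol, backend = c("table", "mmff94"),
                              table = read_parameter_table()) {
  backend <- match.arg(backend)
  if (backend == "mmff94") return(mmff94_assign(mol))
  idx <- match(mol$types, table$type)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1L]
    stop("no table entry for atom ", bad, " (element ",
         mol$elements[bad], ", type '", mol$types[bad], "')")
  }
  mol$charges <- table$charge[idx]
  mol$sigma <- table$sigma[idx]
  mol$epsilon <- table$epsilon[idx]
  attr(mol, "parameter_source") <- "bundled generic table"
  mol
}
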