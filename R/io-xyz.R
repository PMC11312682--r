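#' Read a plain XYZ file
#'
#' Standard XYZ: an atom-count line, a comment line, then `element x y z`
#' rows. Bonds and parameters are left unset.
#'
#' @param path file path.
#' @return A `molecule`.
#' @export
read_xyz <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[seq_len(max(which(nzchar(trimws(lines))), 0L))]
  if (length(lines) < 3L) stop("XYZ file too short: ", path)
  n <- suppressWarnings(as.integer(trimws(lines[1L])))
  if (is.na(n) || n < 1L)
    stop("malformed atom count on line 1 of ", path)
  if (length(lines) < 2L + n)
    stop("count line says ", n, " atoms but only ",
         length(lines) - 2L, " atom rows follow (", path, ")")
  rows <- strsplit(trimws(lines[3:(2L + n)]), "\\s+")
  bad <- which(vapply(rows, length, 1L) < 4L)
  if (length(bad))
    stop("malformed atom row on line ", bad[1L] + 2L, " of ", path)
  elements <- vapply(rows, `[[`, "", 1L)
  xyz <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3L)))
  if (anyNA(xyz)) stop("non-numeric coordinate in ", path)
  molecule(elements, xyz,
           name = tools::file_path_sans_ext(basename(path)))
}

#' Read a Tinker-XYZ (.txyz) file
#'
#' Tinker dialect: a count line, then per-atom rows
#' `index element x y z type bonded-indices...` with 1-based indices.
#' Non-reciprocal bond entries are symmetrized with a warning.
#'
#' @param path file path.
#' @return A `molecule` with atom types and bonds.
#' @export
read_tinker_xyz <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  first <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  n <- suppressWarnings(as.integer(first[1L]))
  if (is.na(n) || n < 1L)
    stop("malformed atom count on line 1 of ", path)
  if (length(lines) < 1L + n)
    stop("count line says ", n, " atoms but only ",
         length(lines) - 1L, " atom rows follow (", path, ")")
  elements <- character(n)
  types <- character(n)
  xyz <- matrix(NA_real_, n, 3L)
  adjacency <- vector("list", n)
  for (i in seq_len(n)) {
    f <- strsplit(trimws(lines[i + 1L]), "\\s+")[[1L]]
    if (length(f) < 5L)
      stop("malformed atom row on line ", i + 1L, " of ", path)
    elements[i] <- f[2L]
    xyz[i, ] <- as.numeric(f[3:5])
    types[i] <- if (length(f) >= 6L) f[6L] else NA_character_
    if (length(f) >= 7L) {
      nb <- as.integer(f[7:length(f)])
      if (anyNA(nb) || any(nb < 1L) || any(nb > n))
        stop("bond index out of range on line ", i + 1L, " of ", path)
      adjacency[[i]] <- nb
    }
  }
  if (anyNA(xyz)) stop("non-numeric coordinate in ", path)
  pairs <- do.call(rbind, lapply(seq_len(n), function(i) {
    if (length(adjacency[[i]])) cbind(i, adjacency[[i]]) else NULL
  }))
  bonds <- NULL
  if (!is.null(pairs) && nrow(pairs)) {
    key <- paste(pairs[, 1L], pairs[, 2L])
    rev_key <- paste(pairs[, 2L], pairs[, 1L])
    if (!all(rev_key %in% key))
      warning("non-reciprocal bond entries in ", path, "; symmetrized")
    bonds <- canonical_bonds(pairs)
  }
  molecule(elements, xyz, bonds = bonds, types = types,
           name = tools::file_path_sans_ext(basename(path)))
}

#' Write molecules or trajectory frames as plain XYZ
#'
#' A single molecule gives one XYZ block; a list of coordinate matrices
#' (frames sharing `mol`'s atoms) gives a multi-frame XYZ file.
#'
#' @param mol a `molecule`.
#' @param path output file path.
#' @param frames optional list of n x 3 coordinate matrices; when given, one
#'   block per frame is written using `mol`'s elements.
#' @param comment comment-line text.
#' @return The path, invisibly.
#' @export
write_xyz <- function(mol, path, frames = NULL, comment = mol$name) {
  if (n_atoms(mol) < 1L) stop("refusing to write an empty molecule")
  blocks <- if (is.null(frames)) list(mol$coords) else frames
  con <- try(file(path, "w"), silent = TRUE)
  if (inherits(con, "try-error")) stop("cannot open for writing: ", path)
  on.exit(close(con))
  for (xyz in blocks) {
    stopifnot(nrow(xyz) == n_atoms(mol))
    writeLines(c(
      as.character(n_atoms(mol)), comment,
      sprintf("%-3s %14.8f %14.8f %14.8f", mol$elements,
              xyz[, 1L], xyz[, 2L], xyz[, 3L])), con)
  }
  invisible(path)
}

#' Write a molecule in Tinker-XYZ format
#'
#' @param mol a `molecule`; atom type labels are written when present.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_tinker_xyz <- function(mol, path) {
  n <- n_atoms(mol)
  adjacency <- lapply(seq_len(n), function(i) integer())
  if (nrow(mol$bonds)) {
    for (r in seq_len(nrow(mol$bonds))) {
      i <- mol$bonds[r, 1L]; j <- mol$bonds[r, 2L]
      adjacency[[i]] <- c(adjacency[[i]], j)
      adjacency[[j]] <- c(adjacency[[j]], i)
    }
  }
  types <- ifelse(is.na(mol$types), "0", mol$types)
  rows <- vapply(seq_len(n), function(i) {
    sprintf("%6d  %-3s %12.6f %12.6f %12.6f %6s %s", i, mol$elements[i],
            mol$coords[i, 1L], mol$coords[i, 2L], mol$coords[i, 3L],
            types[i], paste(sort(adjacency[[i]]), collapse = " "))
  }, "")
  writeLines(c(sprintf("%6d  %s", n, mol$name), rows), path)
  invisible(path)
}
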