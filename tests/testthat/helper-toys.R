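# Small synthetic systems used across the suite.

# single Lennard-Jones atom as a one-atom "molecule"
lj_atom <- function(name = "a", sigma = 3.4, epsilon = 0.238,
                    charge = 0, at = c(0, 0, 0), element = "C") {
  molecule(element, matrix(at, 1, 3), name = name, types = "X",
           charges = charge, sigma = sigma, epsilon = epsilon)
}

# a rigid two-atom toy molecule with chosen parameters
two_atom <- function(name = "t", d = 1, sigma = c(3, 3),
                     epsilon = c(0.1, 0.1), charge = c(0.2, -0.2)) {
  molecule(c("C", "O"), rbind(c(0, 0, 0), c(d, 0, 0)),
           bonds = rbind(c(1, 2)), name = name, types = c("A", "B"),
           charges = charge, sigma = sigma, epsilon = epsilon)
}

# random frame of small rigid molecules in a periodic box, for neighbor
# counting checks; returns the arguments the counting functions take
random_frame <- function(n_mol = 30, edge = 15, atoms_per_mol = 3) {
  sizes <- sample(seq_len(atoms_per_mol), n_mol, replace = TRUE)
  pos <- NULL
  idx <- integer()
  elements <- character()
  for (m in seq_len(n_mol)) {
    base <- runif(3, 0, edge)
    xyz <- matrix(base, sizes[m], 3, byrow = TRUE) +
      matrix(runif(3 * sizes[m], -0.8, 0.8), sizes[m], 3)
    pos <- rbind(pos, xyz %% edge)
    idx <- c(idx, rep(m, sizes[m]))
    elements <- c(elements, sample(c("H", "C", "O"), sizes[m],
                                   replace = TRUE))
  }
  list(positions = pos, molecule_index = idx, elements = elements,
       edge = edge, solute = sample(n_mol, 1))
}
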