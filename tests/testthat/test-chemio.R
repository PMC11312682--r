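test_that("plain XYZ files parse and round-trip", {
  path <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("3", "water",
               "O  0.0  0.4  0.0",
               "H -0.76 -0.18 0.0",
               "H  0.76 -0.21 0.0"), path)
  m <- read_xyz(path)
  expect_equal(n_atoms(m), 3L)
  expect_equal(m$elements, c("O", "H", "H"))
  expect_equal(nrow(m$bonds), 0L)

  out <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(m, out)
  expect_length(readLines(out), 5L)
  back <- read_xyz(out)
  expect_equal(back$coords, m$coords, tolerance = 1e-6)
  expect_identical(back$elements, m$elements)
})

test_that("XYZ count-line violations and unknown elements are rejected", {
  path <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("5", "short", "O 0 0 0", "H 1 0 0", "H 0 1 0",
               "H 0 0 1"), path)
  expect_error(read_xyz(path), "count line says 5")
  writeLines(c("1", "odd", "Xx 0 0 0"), path)
  expect_error(read_xyz(path), "unknown element")
})

test_that("multi-frame XYZ writes one block per frame", {
  m <- fixture("H2O", parameterize = FALSE)
  path <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(m, path, frames = list(m$coords, m$coords + 1))
  expect_length(readLines(path), 10L)
})

test_that("Tinker-XYZ parsing returns types and bonds", {
  path <- withr::local_tempfile(fileext = ".txyz")
  writeLines(c("     3  water",
               "1 O 0.0 0.4 0.0 OW 2 3",
               "2 H -0.76 -0.18 0.0 HW 1",
               "3 H 0.76 -0.21 0.0 HW 1"), path)
  m <- read_tinker_xyz(path)
  expect_equal(nrow(m$bonds), 2L)
  expect_equal(m$types, c("OW", "HW", "HW"))

  writeLines(c("     3  broken",
               "1 O 0.0 0.4 0.0 OW 2 99",
               "2 H -0.76 -0.18 0.0 HW 1",
               "3 H 0.76 -0.21 0.0 HW 1"), path)
  expect_error(read_tinker_xyz(path), "out of range")
})

test_that("Tinker-XYZ round trip preserves coordinates and bonds", {
  for (nm in c("H2O", "HAc", "EtOH")) {
    m <- fixture(nm, parameterize = FALSE)
    path <- withr::local_tempfile(fileext = ".txyz")
    write_tinker_xyz(m, path)
    back <- read_tinker_xyz(path)
    expect_equal(back$coords, m$coords, tolerance = 1e-6)
    expect_identical(back$bonds, m$bonds)
  }
})

test_that("acetic acid fixture has the hand-counted topology", {
  m <- fixture("HAc")
  expect_equal(n_atoms(m), 8L)
  expect_equal(nrow(m$bonds), 7L)
  expect_equal(sort(table(m$elements), decreasing = TRUE),
               sort(table(c("C", "C", "O", "O", "H", "H", "H", "H")),
                    decreasing = TRUE))
})

test_that("fixture set is complete and guards its names", {
  counts <- c(H2O = 3L, Me = 5L, Et = 8L, MeOH = 6L, EtOH = 9L,
              Me2O = 9L, HAc = 8L)
  for (nm in names(counts))
    expect_equal(n_atoms(fixture(nm)), counts[[nm]])
  expect_error(fixture("unknown"), "available")
  expect_true(all(vapply(fixture_names(), function(nm)
    abs(sum(fixture(nm)$charges)) < 1e-10, logical(1))))
})

test_that("VABC volumes match the published contribution sums", {
  expect_equal(vabc_volume(fixture("H2O")), 17.35, tolerance = 1e-10)
  expect_equal(vabc_volume(fixture("Me")), 25.86, tolerance = 1e-10)
  h <- molecule("H", matrix(0, 1, 3))
  expect_equal(vabc_volume(h), 7.24)
})

test_that("VABC is additive over disconnected fragments", {
  w <- fixture("H2O", parameterize = FALSE)
  me <- fixture("Me", parameterize = FALSE)
  both <- molecule(c(w$elements, me$elements),
                   rbind(w$coords, me$coords + 50),
                   bonds = rbind(w$bonds, me$bonds + n_atoms(w)))
  expect_equal(vabc_volume(both), vabc_volume(w) + vabc_volume(me),
               tolerance = 1e-10)
})

test_that("molecule centers obey their definitions", {
  a <- molecule("C", matrix(c(1, 2, 3), 1, 3))
  expect_equal(molecule_center(a), c(1, 2, 3))
  pair <- molecule(c("C", "C"), rbind(c(-2, 0, 0), c(2, 0, 0)))
  expect_equal(molecule_center(pair, "mass"), c(0, 0, 0))

  w <- fixture("H2O")
  manual <- colSums(w$coords * w$masses) / sum(w$masses)
  expect_equal(molecule_center(w, "mass"), manual, tolerance = 1e-12)

  # translation equivariance
  for (i in 1:5) {
    t <- rnorm(3)
    shifted <- translate_molecule(w, t)
    expect_equal(molecule_center(shifted), molecule_center(w) + t,
                 tolerance = 1e-12)
    expect_equal(molecule_center(shifted, "mass"),
                 molecule_center(w, "mass") + t, tolerance = 1e-12)
  }
})

test_that("molecule construction validates its invariants", {
  expect_error(molecule("C", matrix(c(1, 2), 1, 2)), "n x 3")
  expect_error(molecule("C", matrix(Inf, 1, 3)), "finite")
  expect_error(molecule(c("C", "C"), matrix(0, 2, 3),
                        bonds = rbind(c(1, 1))), "self-bonds")
  expect_error(molecule(c("C", "C"), matrix(0, 2, 3),
                        bonds = rbind(c(1, 3))), "out of range")
})
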