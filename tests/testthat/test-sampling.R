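test_that("fibonacci lattice covers the sphere nearly uniformly", {
  expect_error(fibonacci_sphere(0), ">= 1")
  p1 <- fibonacci_sphere(1)
  expect_equal(sum(p1^2), 1, tolerance = 1e-12)

  n <- 144
  pts <- unclass(fibonacci_sphere(n))
  expect_equal(sqrt(rowSums(pts^2)), rep(1, n), tolerance = 1e-12)
  expect_equal(nrow(unique(round(pts, 9))), n)
  # minimum pairwise angle close to the ideal uniform spacing sqrt(4 pi/n)
  cosang <- tcrossprod(pts)
  diag(cosang) <- -1
  min_angle <- acos(max(pmin(cosang, 1)))
  ideal <- sqrt(4 * pi / n)
  expect_gt(min_angle, 0.5 * ideal)
  expect_lt(min_angle, 1.5 * ideal)
  # near-zero centroid means no hemisphere bias
  expect_lt(sqrt(sum(colMeans(pts)^2)), 0.05)
})

test_that("orient_to_axis maps lattice points onto the axis", {
  ex <- c(1, 0, 0)
  expect_equal(orient_to_axis(ex), diag(3), tolerance = 1e-12)
  flipped <- orient_to_axis(-ex) %*% (-ex)
  expect_equal(abs(sum(flipped * ex)), 1, tolerance = 1e-12)
  set.seed(11)
  for (i in 1:25) {
    p <- rnorm(3)
    p <- p / sqrt(sum(p^2))
    sgn <- sample(c(-1, 1), 1)
    rot <- orient_to_axis(p, sign = sgn)
    expect_equal(sum((rot %*% p) * (sgn * ex)), 1, tolerance = 1e-10)
    expect_equal(det(rot), 1, tolerance = 1e-10)  # proper rotation
  }
})

test_that("enumeration yields exactly n_sphere^2 * n_rot configurations", {
  w <- fixture("H2O")
  cfg <- enumerate_configurations(w, w, 3.5, n_sphere = 7, n_rot = 3)
  expect_length(cfg$energies, 7L^2 * 3L)
  expect_equal(configuration_count(cfg), 147L)
  one <- enumerate_configurations(w, w, 3.5, n_sphere = 1, n_rot = 1)
  expect_length(one$energies, 1L)
  expect_error(enumerate_configurations(w, w, 0), "positive")
})

test_that("single-atom pairs are spherically symmetric", {
  a <- lj_atom("a", charge = 0.1)
  b <- lj_atom("b", charge = -0.1)
  cfg <- enumerate_configurations(a, b, 4, n_sphere = 2, n_rot = 2)
  expect_length(cfg$energies, 8L)
  expect_equal(diff(range(cfg$energies)), 0, tolerance = 1e-12)
})

test_that("every generated configuration keeps the center distance", {
  w <- fixture("H2O")
  hac <- fixture("HAc")
  cfg <- enumerate_configurations(w, hac, 4.37, n_sphere = 5, n_rot = 3)
  for (idx in seq_len(configuration_count(cfg))) {
    dc <- dimer_coordinates(cfg, idx)
    sep <- sqrt(sum((colMeans(dc$coords_j) - colMeans(dc$coords_i))^2))
    expect_equal(sep, 4.37, tolerance = 1e-9)
  }
})

test_that("batch energies equal the scalar reference implementation", {
  w <- fixture("H2O")
  hac <- fixture("HAc")
  pp <- pair_params(w, hac)
  cfg <- enumerate_configurations(w, hac, 4.0, n_sphere = 4, n_rot = 3,
                                  params = pp)
  for (idx in seq_len(configuration_count(cfg))) {
    dc <- dimer_coordinates(cfg, idx)
    expect_equal(pair_interaction_energy(dc$coords_i, dc$coords_j,
                                         pp)$total,
                 cfg$energies[idx], tolerance = 1e-10)
  }
})

test_that("Boltzmann averaging obeys its closed forms and limits", {
  expect_equal(boltzmann_average(rep(-3.2, 10), 298), -3.2)
  kT <- boltzmann_constant() * 298
  e2 <- kT * log(2)
  expect_equal(boltzmann_average(c(0, e2), 298), e2 / 3,
               tolerance = 1e-12)
  expect_equal(boltzmann_average(c(0, 1, 2), 1e9), 1, tolerance = 1e-6)
  expect_equal(boltzmann_average(c(0, 1, 2), 1e-4), 0, tolerance = 1e-12)
  expect_error(boltzmann_average(numeric(), 298), "no energies")
  expect_error(boltzmann_average(1, -1), "positive")
})

test_that("Boltzmann average is invariant to constant energy shifts", {
  set.seed(3)
  e <- rnorm(500, sd = 2)
  base <- boltzmann_average(e, 310)
  for (shift in c(-1000, -1, 17, 1e5))
    expect_equal(boltzmann_average(e + shift, 310), base + shift,
                 tolerance = 1e-10)
  # explicit reference energies cancel too
  expect_equal(boltzmann_average(e, 310, reference_energy = 42), base,
               tolerance = 1e-10)
})

test_that("distance scans produce a monotone grid with <E> >= E^C*", {
  w <- fixture("H2O")
  scan <- scan_distance_grid(w, w, 3, 16, 0.5, n_sphere = 6, n_rot = 4)
  expect_equal(nrow(scan), 27L)
  expect_true(all(diff(scan$distance) > 0))
  expect_true(all(scan$e_mean >= scan$e_cstar - 1e-9))
  expect_gte(scan$e_cstar[nrow(scan)], min(scan$e_cstar))

  single <- scan_distance_grid(w, w, 5, 5, 0.5, n_sphere = 4, n_rot = 2)
  expect_equal(nrow(single), 1L)
  expect_error(scan_distance_grid(w, w, 8, 3), "exceed")

  curves <- extract_curves(scan)
  expect_equal(nrow(curves), 27L)
  expect_true(all(curves$e_mean >= curves$e_cstar - 1e-9))
  # LJ-like tail approaches zero from below at large r
  tail5 <- curves$e_cstar[curves$r >= 14]
  expect_true(all(abs(tail5) < 0.05))
})

test_that("refinement recovers the analytic LJ dimer minimum", {
  s <- 3.4
  a <- lj_atom("a", sigma = s, epsilon = 1)
  b <- lj_atom("b", sigma = s, epsilon = 1)
  pp <- pair_params(a, b)
  scan <- scan_distance_grid(a, b, 3, 16, 0.5, n_sphere = 1, n_rot = 1,
                             params = pp)
  ref <- refine_minimum(scan, a, b, params = pp)
  expect_equal(ref$r_min, 2^(1 / 6) * s, tolerance = 0.01)
  expect_lte(ref$best$e_cstar, min(scan$e_cstar) + 1e-12)
  expect_equal(ref$best$e_cstar, -1, tolerance = 1e-3)
})

test_that("rigid-body optimization finds the two-atom LJ minimum", {
  s <- 3.1
  a <- lj_atom("a", sigma = s, epsilon = 0.8)
  b <- lj_atom("b", sigma = s, epsilon = 0.8)
  pp <- pair_params(a, b)
  start_j <- matrix(c(1.5 * s, 0, 0), 1, 3)
  od <- optimize_dimer(a, b, matrix(0, 1, 3), start_j,
                       backend = "rigid", params = pp)
  expect_equal(od$r_min, 2^(1 / 6) * s, tolerance = 1e-3)
  expect_equal(od$e_min, -0.8, tolerance = 1e-6)
})

test_that("minimum-energy ties break to the lowest configuration index", {
  a <- lj_atom("a")
  b <- lj_atom("b")
  cfg <- enumerate_configurations(a, b, 4, n_sphere = 3, n_rot = 2)
  # all equal by symmetry: which.min must pick the first
  expect_equal(which.min(cfg$energies), 1L)
})
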