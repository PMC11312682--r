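test_that("box sizing follows the water reference ratio", {
  expect_equal(box_edge_length(1, 17.35), 30.00^(1 / 3),
               tolerance = 1e-12)
  expect_equal(box_edge_length(400, 17.35), 12000^(1 / 3),
               tolerance = 1e-12)
  # cube-root homogeneity
  expect_equal(box_edge_length(8 * 50, 23), 2 * box_edge_length(50, 23),
               tolerance = 1e-12)
  expect_error(box_edge_length(0, 17), "positive")
  # per-molecule volume of water at 298 K
  expect_equal(box_volume_per_molecule(), 30.00, tolerance = 0.01)
  # the box density realizes one molecule per scaled volume exactly
  v <- vabc_volume(fixture("Me"))
  a <- box_edge_length(400, v)
  expect_equal(a^3 / 400, (30.00 / 17.35) * v, tolerance = 1e-12)
})

test_that("solvent boxes are reproducible and respect minimum spacing", {
  w <- fixture("H2O")
  edge <- box_edge_length(8, vabc_volume(w)) * 2  # generous
  b1 <- build_solvent_box(w, 8, edge, seed = 5)
  b2 <- build_solvent_box(w, 8, edge, seed = 5)
  expect_identical(b1$positions, b2$positions)
  expect_equal(length(b1$molecules), 8L)
  # min interatomic distance between different molecules >= 1.5
  mind <- Inf
  for (m in 1:7) for (k in (m + 1):8) {
    pm <- b1$positions[b1$molecule_index == m, ]
    pk <- b1$positions[b1$molecule_index == k, ]
    for (i in seq_len(nrow(pm))) {
      d <- pk - matrix(pm[i, ], nrow(pk), 3, byrow = TRUE)
      d <- d - edge * round(d / edge)
      mind <- min(mind, sqrt(min(rowSums(d^2))))
    }
  }
  expect_gte(mind, 1.5)
})

test_that("solute insertion removes overlapping solvent per the vdW rule", {
  w <- fixture("H2O")
  hac <- fixture("HAc")
  edge <- box_edge_length(27, vabc_volume(w))
  box <- build_solvent_box(w, 27, edge, seed = 21)
  out <- insert_solute(box, hac, seed = 22)
  expect_equal(out$solute_index, length(out$molecules))
  # independent recount of the overlap rule
  sol_pos <- out$positions[out$molecule_index == out$solute_index, ]
  rad_s <- bondi_radii(hac$elements)
  removed <- 0L
  for (m in seq_along(box$molecules)) {
    pos <- box$positions[box$molecule_index == m, ]
    rad <- bondi_radii(box$molecules[[m]]$elements)
    overlap <- FALSE
    for (i in seq_len(nrow(sol_pos))) {
      d <- pos - matrix(sol_pos[i, ], nrow(pos), 3, byrow = TRUE)
      d <- d - edge * round(d / edge)
      if (any(sqrt(rowSums(d^2)) < 0.8 * (rad_s[i] + rad))) {
        overlap <- TRUE
        break
      }
    }
    removed <- removed + overlap
  }
  expect_equal(attr(out, "removed"), removed)
  expect_equal(length(out$molecules), 27L - removed + 1L)
})

test_that("a solvent molecule at the box center is removed on insertion", {
  w <- fixture("H2O")
  edge <- 20
  center_mol <- list(w$coords - matrix(colMeans(w$coords), 3, 3,
                                       byrow = TRUE) + edge / 2)
  box <- mesopair:::new_simulation_box(w, center_mol, edge)
  out <- insert_solute(box, fixture("Me"))
  expect_equal(attr(out, "removed"), 1L)
  expect_equal(length(out$molecules), 1L)
})

test_that("MD is deterministic, records frames, and wraps positions", {
  w <- fixture("H2O")
  edge <- box_edge_length(16, vabc_volume(w)) * 1.3
  box <- build_solvent_box(w, 16, edge, seed = 31)
  st <- md_settings(equilibration_steps = 50, production_steps = 200,
                    record_interval = 50, cutoff = edge * 0.45)
  t1 <- run_md(box, st, seed = 32)
  t2 <- run_md(box, st, seed = 32)
  expect_equal(length(t1$frames), 4L)
  expect_identical(t1$frames, t2$frames)
  for (f in t1$frames) {
    expect_true(all(f >= 0 & f < edge))
  }
  empty <- run_md(box, md_settings(equilibration_steps = 10,
                                   production_steps = 0,
                                   record_interval = 1,
                                   cutoff = edge * 0.45), seed = 1)
  expect_length(empty$frames, 0L)
})

test_that("the Andersen thermostat holds the target temperature", {
  set.seed(8)
  n <- 10
  mols <- lapply(seq_len(n), function(i) lj_atom(paste0("a", i)))
  pos <- lapply(seq_len(n), function(i)
    matrix(c((i - 1) %% 3, (i - 1) %/% 3 %% 3, (i - 1) %/% 9, 0)[1:3] *
             5 + 2, 1, 3))
  box <- mesopair:::new_simulation_box(NULL, pos, 16, molecules = mols)
  st <- md_settings(temperature = 298, equilibration_steps = 1000,
                    production_steps = 4000, record_interval = 10,
                    thermostat_rate = 25, cutoff = 7)
  traj <- run_md(box, st, seed = 9)
  expect_equal(mean(kinetic_temperature(traj)), 298, tolerance = 0.15)
})

test_that("without thermostat or cutoff the integrator conserves energy", {
  set.seed(12)
  n <- 10
  mols <- lapply(seq_len(n), function(i) lj_atom(paste0("a", i)))
  pos <- lapply(seq_len(n), function(i) matrix(runif(3, 0, 20), 1, 3))
  box <- mesopair:::new_simulation_box(NULL, pos, 20, molecules = mols)
  box <- minimize_box(box, md_settings(cutoff = 9), max_iter = 200)
  st <- md_settings(temperature = 50, equilibration_steps = 0,
                    production_steps = 10000, record_interval = 100,
                    thermostat_rate = 0, cutoff = 1000)
  traj <- run_md(box, st, seed = 13)
  etot <- traj$potential + traj$kinetic
  expect_lt(max(abs(etot - etot[1])) / abs(etot[1]), 0.01)
})

test_that("diverging systems abort with advice to pre-minimize", {
  a <- lj_atom("a", at = c(5, 5, 5))
  b <- lj_atom("b", at = c(5.005, 5, 5))
  box <- mesopair:::new_simulation_box(NULL, list(a$coords, b$coords), 10,
                                       molecules = list(a, b))
  st <- md_settings(equilibration_steps = 0, production_steps = 10,
                    record_interval = 1, cutoff = 4)
  expect_error(run_md(box, st, seed = 1), "pre-minimize")
})

test_that("box minimization descends and fixes overlapping atoms", {
  s <- 3.4
  a <- lj_atom("a", at = c(5, 5, 5), sigma = s, epsilon = 1)
  b <- lj_atom("b", at = c(5 + 0.8 * s, 5, 5), sigma = s, epsilon = 1)
  box <- mesopair:::new_simulation_box(NULL, list(a$coords, b$coords), 40,
                                       molecules = list(a, b))
  out <- minimize_box(box, md_settings(cutoff = 19),
                      max_iter = 2000, force_tol = 1e-4)
  expect_lte(attr(out, "energy_after"), attr(out, "energy_before"))
  d <- sqrt(sum((out$positions[1, ] - out$positions[2, ])^2))
  expect_equal(d, 2^(1 / 6) * s, tolerance = 1e-2)
  # a second pass from the optimum stays put
  again <- minimize_box(out, md_settings(cutoff = 19),
                        max_iter = 100, force_tol = 1e-4)
  d2 <- sqrt(sum((again$positions[1, ] - again$positions[2, ])^2))
  expect_equal(d2, d, tolerance = 1e-3)
})

test_that("neighbor counting honors the inclusive threshold rule", {
  # lone solute
  m <- fixture("Me")
  lone <- list(positions = m$coords %% 20, molecule_index = rep(1, 5),
               elements = m$elements)
  expect_equal(count_neighbors_bruteforce(lone$positions,
                                          lone$molecule_index, 1,
                                          lone$elements,
                                          neighbor_criterion(), 20), 0L)
  # two single atoms: threshold = r_C + r_C + catch = 1.7+1.7+1 = 4.4
  pos <- rbind(c(5, 5, 5), c(9.4, 5, 5))
  args <- list(molecule_index = c(1L, 2L), elements = c("C", "C"),
               criterion = neighbor_criterion(1), edge = 30)
  at <- function(x) {
    p <- pos
    p[2, 1] <- 5 + x
    count_neighbors_bruteforce(p, args$molecule_index, 1L, args$elements,
                               args$criterion, args$edge)
  }
  expect_equal(at(4.4), 1L)       # exactly at threshold: counted
  expect_equal(at(4.3), 1L)
  expect_equal(at(4.4000001), 0L)
})

test_that("neighborship is symmetric and respects periodic images", {
  # straddling the boundary: distance through the wall is small
  pos <- rbind(c(0.2, 5, 5), c(19.8, 5, 5))
  cnt <- count_neighbors_bruteforce(pos, c(1L, 2L), 1L, c("C", "C"),
                                    neighbor_criterion(1), 20)
  expect_equal(cnt, 1L)
  set.seed(77)
  for (i in 1:20) {
    fr <- random_frame(n_mol = 12, edge = 18)
    a <- sample(12, 2)
    ci <- count_neighbors_bruteforce(fr$positions, fr$molecule_index,
                                     a[1], fr$elements,
                                     neighbor_criterion(), fr$edge)
    # i neighbors j iff j neighbors i: compare membership both ways
    near <- function(s, t) {
      ps <- fr$positions[fr$molecule_index == s, , drop = FALSE]
      pt <- fr$positions[fr$molecule_index == t, , drop = FALSE]
      rs <- bondi_radii(fr$elements[fr$molecule_index == s])
      rt <- bondi_radii(fr$elements[fr$molecule_index == t])
      for (u in seq_len(nrow(ps))) {
        d <- pt - matrix(ps[u, ], nrow(pt), 3, byrow = TRUE)
        d <- d - fr$edge * round(d / fr$edge)
        if (any(sqrt(rowSums(d^2)) <= rs[u] + rt + 1)) return(TRUE)
      }
      FALSE
    }
    expect_identical(near(a[1], a[2]), near(a[2], a[1]))
  }
})

test_that("cell-index counts equal brute force on random frames", {
  set.seed(101)
  for (i in 1:200) {
    fr <- random_frame(n_mol = sample(5:40, 1),
                       edge = runif(1, 14, 30))
    crit <- neighbor_criterion(runif(1, 0, 1.5))
    bf <- count_neighbors_bruteforce(fr$positions, fr$molecule_index,
                                     fr$solute, fr$elements, crit,
                                     fr$edge)
    ci <- suppressMessages(
      count_neighbors_cellindex(fr$positions, fr$molecule_index,
                                fr$solute, fr$elements, crit, fr$edge))
    expect_identical(ci, bf)
  }
})

test_that("small boxes fall back to brute force with a notice", {
  fr <- random_frame(n_mol = 5, edge = 8)
  expect_message(
    count_neighbors_cellindex(fr$positions, fr$molecule_index,
                              fr$solute, fr$elements,
                              neighbor_criterion(), fr$edge),
    "brute force")
})

test_that("coordination estimates are running means of frame counts", {
  w <- fixture("H2O")
  edge <- box_edge_length(16, vabc_volume(w)) * 1.2
  box <- build_solvent_box(w, 16, edge, seed = 41)
  box <- insert_solute(box, fixture("MeOH"), seed = 42)
  st <- md_settings(equilibration_steps = 50, production_steps = 300,
                    record_interval = 30, cutoff = edge * 0.45)
  traj <- run_md(box, st, seed = 43)
  est <- estimate_coordination_number(traj, method = "bruteforce")
  expect_equal(est$z, mean(est$per_frame_counts), tolerance = 1e-12)
  expect_equal(est$running_mean,
               cumsum(est$per_frame_counts) /
                 seq_along(est$per_frame_counts), tolerance = 1e-12)
  expect_equal(est$n_frames, length(traj$frames))
  empty <- traj
  empty$frames <- list()
  expect_error(estimate_coordination_number(empty), "no recorded frames")
})

test_that("md settings validate their ranges", {
  expect_error(md_settings(timestep = 0), "timestep")
  expect_error(md_settings(production_steps = 10, record_interval = 20),
               "record_interval")
})
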