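test_that("differential pair energies follow the excess definition", {
  expect_equal(differential_energy(-4, -4, -4), 0)
  expect_equal(differential_energy(-4, -2, -3), 0)
  expect_equal(differential_energy(-6.8, -6.1, -6.5), -0.05,
               tolerance = 1e-12)
})

test_that("coordination-weighted differentials reduce and extend", {
  nm <- c("w", "x")
  e <- matrix(c(-2, -1, -1, -4), 2, 2, dimnames = list(nm, nm))
  z1 <- matrix(1, 2, 2, dimnames = list(nm, nm))
  expect_equal(differential_energy_z(e, z1, "w", "x"),
               differential_energy(-2, -4, -1))
  z <- matrix(c(3, 4, 2, 3), 2, 2, dimnames = list(nm, nm))
  # Z_wx = 2, Z_xw = 4, Z_ww = Z_xx = 3
  expect_equal(differential_energy_z(e, z, "w", "x"),
               0.5 * (2 * -1 + 4 * -1) - 0.5 * (3 * -2 + 3 * -4))
  expect_equal(differential_energy_z(e, z, "w", "x"), 6)
  # all Z equal z0 and e_ij the mean of the self terms -> 0
  e2 <- matrix(c(-2, -3, -3, -4), 2, 2, dimnames = list(nm, nm))
  z0 <- matrix(5, 2, 2, dimnames = list(nm, nm))
  expect_equal(differential_energy_z(e2, z0, "w", "x"), 0)
  # self pairs vanish identically
  expect_equal(differential_energy_z(e, z, "w", "w"), 0)
  expect_equal(differential_energy_z(e, z, "x", "x"), 0)
  expect_error(differential_energy_z(e, z, "nope", "x"), "no entry")
})

test_that("Flory-Huggins parameters scale as Delta E / kB T", {
  expect_equal(flory_huggins(0, 298), 0)
  kT298 <- boltzmann_constant() * 298
  expect_equal(flory_huggins(kT298, 298), 1, tolerance = 1e-12)
  expect_equal(flory_huggins(-0.296095, 298), -0.5, tolerance = 1e-4)
  # inverse proportionality in T
  expect_equal(flory_huggins(0.7, 2 * 313), flory_huggins(0.7, 313) / 2,
               tolerance = 1e-12)
})

test_that("the chi conversion coefficient is the 0.286 reciprocal", {
  expect_equal(conversion_coefficient(), 3.4965)
  expect_equal(conversion_coefficient() * 0.286, 1, tolerance = 1e-4)
  expect_equal(conversion_coefficient(Inf), 3.4965034965034965,
               tolerance = 1e-12)
})

test_that("DPD repulsions reproduce the Groot-Warren limits", {
  expect_equal(dpd_repulsion(0, 3, 298, 300), 24.83, tolerance = 0.005)
  expect_equal(dpd_repulsion(0, 3, 300, 300), 25)
  expect_equal(dpd_repulsion(1, 3, 300, 300), 28.4965)
  expect_equal(dpd_repulsion(0, 5, 300, 300), 15)
})

test_that("particle-set scaling pins the smallest off-diagonal", {
  nm <- c("A", "B", "C")
  raw <- matrix(24.83, 3, 3, dimnames = list(nm, nm))
  raw["A", "B"] <- raw["B", "A"] <- 20
  raw["A", "C"] <- raw["C", "A"] <- 26
  raw["B", "C"] <- raw["C", "B"] <- 23
  ps <- scale_particle_set(raw)
  expect_equal(min(ps$a[upper.tri(ps$a)]), 24.83 - 20)
  expect_equal(diag(ps$a), rep(24.83, 3), ignore_attr = TRUE)
  expect_equal(ps$scaling$base_pair, "A-B")
  # ranking preserved
  ord_raw <- order(raw[upper.tri(raw)])
  ord_new <- order(ps$a[upper.tri(ps$a)])
  expect_identical(ord_raw, ord_new)
  # already at deviation 20: unchanged
  raw2 <- raw
  raw2["A", "B"] <- raw2["B", "A"] <- 4.83
  ps2 <- scale_particle_set(raw2)
  expect_equal(ps2$scaling$factor, 1, tolerance = 1e-12)
  expect_equal(ps2$a, raw2, tolerance = 1e-12)
  # degenerate: all off-diagonals equal the diagonal
  flat <- matrix(24.83, 2, 2, dimnames = list(nm[1:2], nm[1:2]))
  expect_error(scale_particle_set(flat), "undefined")
})

test_that("the conservative DPD force is soft, local and antisymmetric", {
  expect_equal(dpd_conservative_force(c(1, 0, 0), 25), c(0, 0, 0))
  expect_equal(dpd_conservative_force(c(0.5, 0, 0), 25),
               c(12.5, 0, 0))
  r <- c(0.3, -0.2, 0.1)
  expect_equal(dpd_conservative_force(r, 18),
               -dpd_conservative_force(-r, 18), tolerance = 1e-12)
  # continuity at the cutoff
  just_in <- dpd_conservative_force(c(1 - 1e-9, 0, 0), 25)
  expect_lt(sqrt(sum(just_in^2)), 1e-7)
  expect_error(dpd_conservative_force(c(0, 0, 0), 25), "zero separation")
})

test_that("particle sets export and re-import losslessly", {
  nm <- c("H2O", "MeOH", "Me2O", "Me", "Et", "EtOH")
  set.seed(5)
  raw <- matrix(0, 6, 6, dimnames = list(nm, nm))
  raw[upper.tri(raw)] <- runif(15, 20, 40)
  raw <- raw + t(raw)
  diag(raw) <- 24.83
  ps <- scale_particle_set(raw)
  prefix <- file.path(withr::local_tempdir(), "set")
  export_particle_set(ps, prefix)
  tab <- read.csv(paste0(prefix, "_a.csv"))
  expect_equal(dim(tab), c(6L, 7L))
  meta <- jsonlite::fromJSON(paste0(prefix, "_meta.json"))
  expect_true(nzchar(meta$scaling$base_pair))
  back <- read_particle_set(prefix)
  expect_equal(back$a, ps$a, tolerance = 1e-12)
  expect_equal(back$scaling$base_pair, ps$scaling$base_pair)
})

test_that("build_particle_set chains the full mesoscopic mapping", {
  nm <- c("w", "m")
  e <- matrix(c(-6.8, -6.5, -6.5, -6.1), 2, 2, dimnames = list(nm, nm))
  z <- matrix(c(11, 8, 15, 11.5), 2, 2, dimnames = list(nm, nm))
  ps <- build_particle_set(e, z)
  chi <- attr(ps, "chi")
  expect_equal(diag(chi), c(0, 0), ignore_attr = TRUE)
  manual_delta <- 0.5 * (z["w", "m"] + z["m", "w"]) * -6.5 -
    0.5 * (11 * -6.8 + 11.5 * -6.1)
  expect_equal(chi["w", "m"], flory_huggins(manual_delta, 298),
               tolerance = 1e-12)
  # zij_one collapses to the unweighted differential
  ps1 <- build_particle_set(e, z, zij_one = TRUE)
  chi1 <- attr(ps1, "chi")
  expect_equal(chi1["w", "m"],
               flory_huggins(differential_energy(-6.8, -6.1, -6.5), 298),
               tolerance = 1e-12)
})
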