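test_that("neutral pair at combined Rmin sits at minus the combined well depth", {
  mol <- one_site_molecule()
  p <- one_site_params()
  comb <- combine_lj("S", "SOD", p)
  # ion placed exactly at Rmin below the sulfur (approach is along -z here)
  e <- pair_interaction_energy(mol, c(0, 0, -comb[["rmin"]]), p,
                               ion_charge = 0)
  expect_equal(e, -comb[["well_depth"]], tolerance = 1e-12)
})

test_that("uncharged interaction decays to zero at long range", {
  mol <- one_site_molecule()
  p <- one_site_params()
  e <- pair_interaction_energy(mol, c(0, 0, -100), p, ion_charge = 0)
  expect_lt(abs(e), 1e-6)
})

test_that("energy matches an independent per-pair brute-force sum", {
  set.seed(42)
  types <- c("S", "CT3", "SOD")
  for (rep in 1:8) {
    atoms <- data.frame(
      name = paste0("X", 1:5),
      type = sample(c("S", "CT3"), 5, replace = TRUE),
      element = "S",
      x = stats::runif(5, -3, 3), y = stats::runif(5, -3, 3),
      z = stats::runif(5, -3, 3))
    # enforce the 0.5 A minimum separation invariant by rejection
    while (min(stats::dist(atoms[, c("x", "y", "z")])) < 0.6) {
      atoms$x <- stats::runif(5, -3, 3)
      atoms$y <- stats::runif(5, -3, 3)
      atoms$z <- stats::runif(5, -3, 3)
    }
    mol <- molecule_geometry(atoms, "rand")
    prm <- parameter_set(
      lj_types = data.frame(type = types,
                            well_depth = stats::runif(3, 0.01, 0.5),
                            rmin_half = stats::runif(3, 1, 2.2)),
      charges = data.frame(molecule = "rand", atom = atoms$name,
                           charge = stats::runif(5, -0.3, 0.3)),
      overrides = if (rep %% 2 == 0)
        data.frame(type_a = "S", type_b = "SOD",
                   well_depth = 13.4, rmin = 2.8) else
        data.frame(type_a = character(), type_b = character(),
                   well_depth = numeric(), rmin = numeric()))
    ion <- c(6, 6, 6)
    expect_equal(pair_interaction_energy(mol, ion, prm),
                 brute_force_energy(mol, ion, prm), tolerance = 1e-10)
  }
})

test_that("near-coincident ion triggers the singularity guard", {
  mol <- one_site_molecule()
  expect_error(pair_interaction_energy(mol, c(0, 0, 0.05), one_site_params()),
               "0.1 Angstrom")
})

test_that("approach series has exact distances and the documented count", {
  mol <- analog_geometry("methylthioethane")
  cfg <- build_approach_series(mol)
  expect_equal(nrow(cfg), 51L)
  expect_equal(cfg$distance, seq(2, 7, by = 0.1))
  # placed ion positions honour the anchor-distance contract exactly
  anchor <- mol$atoms[mol$atoms$name == "SD", c("x", "y", "z")]
  d <- sqrt((cfg$x - anchor$x)^2 + (cfg$y - anchor$y)^2 +
            (cfg$z - anchor$z)^2)
  expect_equal(d, cfg$distance, tolerance = 1e-12)

  cfg2 <- build_approach_series(mol, 4.0, 5.0, 0.5)
  expect_equal(cfg2$distance, c(4.0, 4.5, 5.0))
  expect_error(build_approach_series(mol, 2.0, 2.0), "r_start")
  expect_error(build_approach_series(mol, anchor_atom = "ZZ"), "ZZ")
})

test_that("energy curves are invariant under rigid-body transformation", {
  set.seed(7)
  mol <- analog_geometry("methylthioethane")
  p <- default_parameter_set()
  cfg <- build_approach_series(mol, 2.5, 6.5, 0.5)
  e0 <- energy_curve(cfg, mol, p)$energies
  for (rep in 1:3) {
    R <- random_rotation(); tr <- stats::rnorm(3, sd = 10)
    a2 <- mol$atoms
    xyz2 <- apply_rigid(as.matrix(a2[, c("x", "y", "z")]), R, tr)
    a2$x <- xyz2[, 1]; a2$y <- xyz2[, 2]; a2$z <- xyz2[, 3]
    mol2 <- molecule_geometry(a2, mol$label)
    ion2 <- apply_rigid(as.matrix(cfg[, c("x", "y", "z")]), R, tr)
    cfg2 <- data.frame(distance = cfg$distance, x = ion2[, 1],
                       y = ion2[, 2], z = ion2[, 3])
    expect_equal(energy_curve(cfg2, mol2, p)$energies, e0, tolerance = 1e-9)
  }
})

test_that("curve source labels track the presence of overrides", {
  mol <- analog_geometry("methylthioethane")
  cfg <- build_approach_series(mol, 2.5, 6.5, 0.5)
  expect_identical(energy_curve(cfg, mol, default_parameter_set())$source_label,
                   "mm_default")
  expect_identical(
    energy_curve(cfg, mol, default_parameter_set(TRUE))$source_label,
    "mm_nbfix")
})

test_that("deepening the pair well strictly lowers the curve minimum", {
  mol <- analog_geometry("methylthioethane")
  cfg <- build_approach_series(mol)
  base <- default_parameter_set()
  mins <- vapply(c(5, 8, 11, 14), function(eps) {
    ov <- data.frame(type_a = "S", type_b = "SOD",
                     well_depth = eps, rmin = 2.8)
    min(energy_curve(cfg, mol, with_override(base, ov))$energies)
  }, numeric(1))
  expect_true(all(diff(mins) < 0))
})

test_that("zero-charge zero-epsilon system yields an identically zero curve", {
  mol <- one_site_molecule()
  p <- one_site_params(eps_s = 0, eps_ion = 0)
  cfg <- build_approach_series(mol, 2, 7, 0.5, anchor_atom = "S1")
  expect_equal(energy_curve(cfg, mol, p, ion_charge = 0)$energies,
               rep(0, nrow(cfg)))
})

test_that("curve TSV I/O round-trips values and provenance label", {
  c0 <- as_energy_curve(seq(2, 4, 0.5), c(5, -1, -3, -2, -1.5), "mm_nbfix")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_curve(c0, f)
  c1 <- read_curve(f)
  expect_equal(c1$distances, c0$distances)
  expect_equal(c1$energies, c0$energies)
  expect_identical(c1$source_label, "mm_nbfix")
})

test_that("geometry invariants and XYZ round trip hold", {
  expect_error(molecule_geometry(
    data.frame(name = c("A", "B"), type = "S", element = "S",
               x = c(0, 0.1), y = 0, z = 0), "clash"), "0.5")
  mol <- analog_geometry("methanethiol")
  f <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(mol, f)
  mol2 <- read_xyz(f)
  expect_equal(as.matrix(mol2$atoms[, c("x", "y", "z")]),
               as.matrix(mol$atoms[, c("x", "y", "z")]),
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_identical(mol2$atoms$type, mol$atoms$type)
  expect_identical(mol2$atoms$name, mol$atoms$name)
})
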