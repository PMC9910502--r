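test_that("built-in materials carry the reference optical constants", {
  tab <- builtin_materials()
  expect_setequal(names(tab)[1:3], c("air", "muscle", "lung_parenchyma"))

  expect_equal(delta_at(get_material(tab, "air"), 60), 6.91e-11)
  expect_equal(delta_at(get_material(tab, "muscle"), 60), 6.66e-8)
  expect_equal(delta_at(get_material(tab, "lung_parenchyma"), 60), 3.37e-8)

  expect_equal(get_material(tab, "air")$density, 0.0012)
  expect_equal(get_material(tab, "muscle")$density, 1.05)
  expect_equal(get_material(tab, "lung_parenchyma")$density, 0.53)

  # delta per unit density is an elemental-composition property: muscle and
  # parenchyma (both soft tissue) must agree closely -- a consistency check
  # on the three printed decrements
  dpr_mus <- 6.66e-8 / 1.05
  dpr_par <- 3.37e-8 / 0.53
  expect_lt(abs(dpr_mus - dpr_par) / dpr_mus, 0.01)
})

test_that("delta interpolation follows the 1/E^2 free-electron scaling", {
  mus <- get_material(builtin_materials(), "muscle")
  expect_equal(delta_at(mus, 120), 6.66e-8 / 4)
  expect_equal(delta_at(mus, 30), 6.66e-8 * 4)
  # monotone decreasing in energy
  E <- seq(20, 150, by = 5)
  expect_true(all(diff(delta_at(mus, E)) < 0))
  expect_error(delta_at(mus, 0), "energy")
})

test_that("mu interpolation is log-linear with exact anchors", {
  mus <- get_material(builtin_materials(), "muscle")
  tab <- mus$mu_table
  # endpoint identity at every tabulated energy
  expect_equal(mu_at(mus, tab[, 1]), tab[, 2])
  # two-point oracle at a midpoint energy
  i <- which(tab[, 1] == 50)
  Emid <- sqrt(50 * 60)  # log-midpoint of the bracketing rows
  hand <- unname(exp((log(tab[i, 2]) + log(tab[i + 1, 2])) / 2))
  expect_equal(mu_at(mus, Emid), hand, tolerance = 1e-12)
  # vacuum-like material
  vac <- material("void", 1e-6, delta_table = cbind(60, 0))
  expect_identical(mu_at(vac, 60), 0)
  expect_identical(mu_at(vac, 17.3), 0)
})

test_that("material tables load from delimited text and merge over built-ins", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("material density energy_keV delta mu_per_mm",
               "muscle 1.05 60 6.66e-8 0.0215"), f)
  tab <- load_material_table(f)
  expect_equal(delta_at(get_material(tab, "muscle"), 60), 6.66e-8)
  expect_equal(mu_at(get_material(tab, "muscle"), 60), 0.0215)
  # built-ins still present
  expect_true("lung_parenchyma" %in% names(tab))

  # header-only file returns the built-ins unchanged
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines("material density energy_keV delta mu_per_mm", f2)
  tab2 <- load_material_table(f2)
  expect_equal(names(tab2), names(builtin_materials()))

  # non-increasing energies are rejected
  f3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("material density energy_keV delta mu_per_mm",
               "muscle 1.05 60 6.66e-8 0.0215",
               "muscle 1.05 40 1.5e-7 0.03"), f3)
  expect_error(load_material_table(f3), "strictly increasing")

  # duplicate (material, energy) is rejected
  f4 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("material density energy_keV delta mu_per_mm",
               "muscle 1.05 60 6.66e-8 0.0215",
               "muscle 1.05 60 6.66e-8 0.0215"), f4)
  expect_error(load_material_table(f4), "duplicate")

  # mass attenuation coefficients are converted with the declared density
  f5 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("material density energy_keV delta mu_over_rho",
               "gel 1.0 60 3.0e-8 0.2048"), f5)
  tab5 <- load_material_table(f5)
  expect_equal(mu_at(get_material(tab5, "gel"), 60), 0.2048 * 1.0 / 10)
})

test_that("material tables round-trip through write/load bit-identically", {
  tab <- builtin_materials()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_material_table(tab, f)
  tab2 <- load_material_table(f)
  for (nm in names(tab)) {
    m1 <- get_material(tab, nm); m2 <- get_material(tab2, nm)
    E <- unique(c(m1$delta_table[, 1], m1$mu_table[, 1]))
    expect_identical(delta_at(m1, E), delta_at(m2, E))
    expect_identical(mu_at(m1, E), mu_at(m2, E))
  }
})

test_that("material constructor enforces its invariants", {
  expect_error(material("x", -1, cbind(60, 1e-8)), "density")
  expect_error(material("x", 1, cbind(60, -1e-8)), "delta")
  expect_error(material("x", 1, cbind(c(60, 40), c(1e-8, 2e-8))),
               "strictly increasing")
  expect_error(material_table(list(material("a", 1, cbind(60, 0)),
                                   material("a", 1, cbind(60, 0)))),
               "duplicate")
  expect_error(get_material(builtin_materials(), "adamantium"), "unknown")
})
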