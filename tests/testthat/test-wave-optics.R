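test_that("transmission function implements phi = -(2 pi / lambda) sum delta t", {
  tab <- builtin_materials()
  # vacuum-like ray: no phase, no attenuation
  g <- grid_spec(0.01, 1)
  void <- material("void", 1e-9, delta_table = cbind(60, 0))
  tabv <- material_table(list(void))
  tm <- thickness_map(g, list(void = rep(10, g$n)), 10)
  wf <- transmission_function(tm, tabv, 60)
  expect_equal(Mod(wf$samples), rep(1, g$n))
  expect_equal(Arg(wf$samples), rep(0, g$n))

  # 100 mm of uniform parenchyma: scalar evaluation of the printed formula
  tmp <- thickness_map(g, list(lung_parenchyma = rep(100, g$n)), 100)
  wfp <- transmission_function(tmp, tab, 60)
  phi_expected <- -(2 * pi / lam60) * 3.37e-8 * 100  # about -1.025e3 rad
  expect_equal(phi_expected, -1024.9, tolerance = 1e-3)
  # compare phases modulo 2 pi (stored phase is wrapped)
  dphi <- Arg(wfp$samples[1] * exp(-1i * phi_expected))
  expect_lt(abs(dphi), 1e-6)
  # Beer-Lambert amplitude
  mu <- mu_at(get_material(tab, "lung_parenchyma"), 60)
  expect_equal(Mod(wfp$samples[1])^2, exp(-mu * 100), tolerance = 1e-12)

  # on-axis phase of the airway relative to the parenchyma background
  tma <- project_scene(airway_scene(0.1, extent = 6), grid_spec(0.0025, 6))
  wfa <- transmission_function(tma, tab, 60)
  i0 <- which.min(abs(wfa$grid$x))
  iref <- 10  # parenchyma-only margin
  rel <- Arg(wfa$samples[i0] / wfa$samples[iref])
  rel_expected <- -(2 * pi / lam60) *
    ((6.91e-11 - 3.37e-8) * 2 + (6.66e-8 - 3.37e-8) * 0.2)
  expect_equal(rel_expected, 18.45, tolerance = 1e-3)
  expect_equal(rel, Arg(exp(1i * rel_expected)), tolerance = 1e-3)

  # passive object: no gain anywhere
  expect_true(all(Mod(wfa$samples) <= 1 + 1e-12))
})

test_that("z = 0 propagation is the identity and uniform fields are eigenfunctions", {
  g <- grid_spec(0.001, 1)
  wf <- compact_test_field(g)
  expect_identical(fresnel_propagate(wf, propagation_plan(0))$samples,
                   wf$samples)
  # spatially uniform field: unchanged up to a global phase
  u <- wavefront(rep(0.7 + 0i, g$n), g, lam60)
  pu <- fresnel_propagate(u, propagation_plan(5e4))
  expect_equal(Mod(pu$samples), rep(0.7, g$n), tolerance = 1e-9)
  ratio <- pu$samples / u$samples
  expect_lt(max(Mod(ratio - ratio[1])), 1e-9)
})

test_that("energy is conserved on the padded grid (Parseval)", {
  g <- grid_spec(0.001, 1)
  wf <- compact_test_field(g)
  pad <- pbisim:::pad_edge(wf$samples, 2)
  out <- fresnel_propagate(wf, propagation_plan(5e4), crop = FALSE)
  e_in <- mean(Mod(pad$padded)^2)
  e_out <- mean(Mod(out$samples)^2)
  expect_lt(abs(e_out - e_in) / e_in, 1e-9)
})

test_that("propagation is unitary and forms a semigroup", {
  g <- grid_spec(0.001, 1.024)
  wf <- compact_test_field(g)
  z1 <- 3e4; z2 <- 5e4
  two_step <- fresnel_propagate(fresnel_propagate(wf, propagation_plan(z1)),
                                propagation_plan(z2))
  one_step <- fresnel_propagate(wf, propagation_plan(z1 + z2))
  expect_lt(max(Mod(two_step$samples - one_step$samples)), 1e-6)

  back <- fresnel_propagate(fresnel_propagate(wf, propagation_plan(z1)),
                            propagation_plan(-z1, inverse = TRUE))
  expect_lt(max(Mod(back$samples - wf$samples)) / max(Mod(wf$samples)), 1e-6)
  # inverse propagation must be requested explicitly
  expect_error(propagation_plan(-100), "inverse")
})

test_that("the spectral propagator matches the analytic Gaussian solution", {
  # closed form: a Gaussian exp(-x^2 / 2 sigma^2) propagates to
  # sqrt(pi/(a-b)) / sqrt(i lambda z) * exp(x^2 a b / (a - b)),
  # a = 1/(2 sigma^2), b = i pi / (lambda z)
  g <- grid_spec(0.001, 1.024)
  sigma <- 0.05
  wf <- wavefront(exp(-g$x^2 / (2 * sigma^2)), g, lam60)
  for (z in c(5e4, 2e5)) {
    num <- fresnel_propagate(wf, propagation_plan(z, padding_factor = 4))
    a <- 1 / (2 * sigma^2); b <- 1i * pi / (lam60 * z)
    ana <- sqrt(pi / (a - b)) / sqrt(1i * lam60 * z) *
      exp(g$x^2 * a * b / (a - b))
    expect_lt(max(Mod(num$samples - ana)), 1e-9)
  }
})

test_that("the spectral propagator agrees with direct Fresnel quadrature", {
  # configuration near the critical distance z* = N dx^2 / lambda, where
  # the sampled chirp kernel of the direct integral is Nyquist-adequate
  g <- grid_spec(0.001, 2.048)
  u <- (1 - 0.3 * exp(-g$x^2 / (2 * 0.08^2))) *
    exp(1i * 0.5 * exp(-g$x^2 / (2 * 0.1^2)))
  wf <- wavefront(u, g, lam60)
  z_crit <- 4096 * 0.001^2 / lam60
  for (zf in c(0.8, 1, 1.3)) {
    spectral <- fresnel_propagate(wf, propagation_plan(zf * z_crit))
    direct <- fresnel_integral_direct(wf, zf * z_crit)
    I_s <- Mod(spectral$samples)^2
    I_d <- Mod(direct$samples)^2
    expect_lt(max(abs(I_s - I_d)) / max(I_s), 1e-3)
  }
})

test_that("direct quadrature reproduces the far-field single-slit pattern", {
  # narrow slit, z far beyond the near field: intensity zeros at multiples
  # of lambda z / w
  g <- grid_spec(0.001, 2.048)
  w_slit <- 0.04
  u <- as.numeric(abs(g$x) <= w_slit / 2) + 0i
  wf <- wavefront(u, g, lam60)
  z <- 4096 * 0.001^2 / lam60 * 2  # deep Fraunhofer for this slit
  out <- fresnel_integral_direct(wf, z, padding_factor = 2)
  I <- Mod(out$samples)^2
  zero1 <- lam60 * z / w_slit
  # first minimum located within 10% of the sinc zero
  i_min <- which(diff(sign(diff(I))) > 0) + 1L  # local minima
  x_min <- min(abs(g$x[i_min[abs(g$x[i_min]) > 0.2 * zero1]]))
  expect_lt(abs(x_min - zero1) / zero1, 0.1)
  # identity bypass and size guard
  expect_identical(fresnel_integral_direct(wf, 0)$samples, wf$samples)
  big <- wavefront(rep(1 + 0i, 8192), grid_spec(0.001, 8.192), lam60)
  expect_error(fresnel_integral_direct(big, z), "4096")
})

test_that("propagation refuses under-sampled grids with the computed bound", {
  g <- grid_spec(0.02, 4)
  wf <- wavefront(rep(1 + 0i, g$n), g, lam60)
  expect_error(fresnel_propagate(wf, propagation_plan(12000)),
               "sampling violation")
})

test_that("intensity normalization uses the declared background region", {
  g <- grid_spec(0.01, 2)
  u <- rep(0.5 + 0i, g$n)
  wf <- wavefront(u, g, lam60)
  img <- intensity_image(wf)
  expect_equal(img$values, rep(1, g$n))
  # absorption-only slab at z = 0: I/I0 = exp(-mu t) against an empty region
  tab <- builtin_materials()
  mus <- get_material(tab, "muscle")
  half <- c(rep(0, g$n / 2), rep(10, g$n / 2))
  tm <- thickness_map(g, list(muscle = half, air = 10 - half), 10)
  wf2 <- transmission_function(tm, tab, 60)
  img2 <- intensity_image(wf2, normalization_region = seq_len(20))
  mu_eff <- mu_at(mus, 60) - mu_at(get_material(tab, "air"), 60)
  expect_equal(img2$values[g$n], exp(-mu_eff * 10), tolerance = 1e-6)
  # degenerate normalization region
  dark <- wavefront(c(rep(0 + 0i, 10), rep(1 + 0i, g$n - 10)), g, lam60)
  expect_error(intensity_image(dark, normalization_region = 1:10),
               "non-positive")
})
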