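test_that("detector blur is a normalized Gaussian with semigroup property", {
  img <- airway_intensity(0.2, pitch = 0.005)
  # identity at sigma = 0
  expect_identical(apply_detector_blur(img, 0)$values, img$values)
  # global mean preserved (kernel normalized, edge replication)
  b <- apply_detector_blur(img, 0.02)
  expect_equal(mean(b$values), mean(img$values), tolerance = 1e-3)
  # blurring twice with s1, s2 equals once with sqrt(s1^2 + s2^2); checked
  # on a compact bump so edge replication plays no role
  g <- grid_spec(0.005, 8)
  bump <- pbisim:::intensity_image_from_values(
    1 + 0.5 * exp(-g$x^2 / (2 * 0.05^2)), g)
  b12 <- apply_detector_blur(apply_detector_blur(bump, 0.015), 0.02)
  bq <- apply_detector_blur(bump, sqrt(0.015^2 + 0.02^2))
  expect_lt(max(abs(b12$values - bq$values)), 1e-6)
  # under-resolved kernel warns
  expect_warning(apply_detector_blur(img, 0.001), "under-resolved")
})

test_that("blur reduces fringe visibility, strongly so beyond sigma_FZ", {
  img <- airway_intensity(0.2)
  sfz <- fresnel_zone_width(lam60, 12000)
  v0 <- fringe_visibility(extract_profile(img))
  v_half <- fringe_visibility(extract_profile(apply_detector_blur(img, sfz / 2)))
  v_two <- fringe_visibility(extract_profile(apply_detector_blur(img, 2 * sfz)))
  expect_lte(v_half, v0)
  expect_lt(v_two, v_half)
})

test_that("pixel binning averages footprints and preserves the mean", {
  img <- airway_intensity(0.2, pitch = 0.005)
  px <- bin_to_pixels(img, 0.05)
  expect_equal(px$grid$pitch, 0.05)
  expect_equal(mean(px$values), mean(img$values), tolerance = 1e-12)
  # uniform image stays uniform
  g <- grid_spec(0.005, 2)
  uni <- intensity_image(wavefront(rep(1 + 0i, g$n), g, lam60))
  expect_equal(unique(bin_to_pixels(uni, 0.05)$values), 1)
  # single-sample spike of height h in a k-sample footprint
  v <- rep(1, g$n); v[13] <- 3
  spike <- pbisim:::intensity_image_from_values(v, g)
  k <- 10
  pxs <- bin_to_pixels(spike, 0.05)
  expect_equal(max(pxs$values), 1 + (3 - 1) / k, tolerance = 1e-12)
  # non-integer pitch ratio refused with a suggestion
  expect_error(bin_to_pixels(img, 0.012), "integer multiple")
})

test_that("expected counts follow fluence x pixel area x transmission", {
  g <- grid_spec(0.05, 1)
  uni <- pbisim:::intensity_image_from_values(rep(1, g$n), g)
  expect_equal(unique(expected_counts(uni, 3.6e6, 0.05)), 9000)
  expect_equal(unique(expected_counts(uni, 0, 0.05)), 0)
  # linear in pitch^2
  expect_equal(unique(expected_counts(uni, 3.6e6, 0.1)),
               4 * unique(expected_counts(uni, 3.6e6, 0.05)))
  # transmission scales counts; opaque region counts are zero (no scatter)
  expect_equal(unique(expected_counts(uni, 3.6e6, 0.05, 0.5)), 4500)
  zero <- pbisim:::intensity_image_from_values(rep(0, g$n), g)
  expect_equal(unique(expected_counts(zero, 3.6e6, 0.05)), 0)
})

test_that("Poisson counting noise is seeded, unbiased and dispersion-correct", {
  n <- 1e5
  counts <- poisson_counts(rep(9000, n), seed = 42)
  counts2 <- poisson_counts(rep(9000, n), seed = 42)
  expect_identical(counts, counts2)
  expect_false(identical(counts, poisson_counts(rep(9000, n), seed = 43)))
  # sample mean within 3 standard errors; Fano factor near 1
  expect_lt(abs(mean(counts) - 9000), 3 * sqrt(9000 / n))
  expect_gt(var(counts) / mean(counts), 0.97)
  expect_lt(var(counts) / mean(counts), 1.03)
  # relative noise at unity transmission ~ 1/sqrt(fluence * pitch^2)
  rel <- sd(counts) / mean(counts)
  expect_equal(rel, 1 / sqrt(3.6e6 * 0.05^2), tolerance = 0.01)
  expect_identical(poisson_counts(rep(0, 10), seed = 1), rep(0L, 10))
  expect_error(poisson_counts(c(-1, 2), seed = 1), ">= 0")
  # caller RNG state is untouched
  set.seed(7); a <- runif(1)
  set.seed(7); invisible(poisson_counts(rep(5, 3), seed = 1)); b <- runif(1)
  expect_identical(a, b)
})

test_that("higher fluence strictly lowers the empirical coefficient of variation", {
  img <- bin_to_pixels(airway_intensity(0.2, pitch = 0.005), 0.05)
  cv <- vapply(c(1e5, 1e6, 1e7), function(fl) {
    det <- detect_image(img, detector_model(fluence = fl, seed = 11),
                        background_transmission = 0.34)
    stats::sd(det$counts) / mean(det$counts)
  }, numeric(1))
  expect_true(all(diff(cv) < 0))
})

test_that("the display operator windows to [0,1] and sharpens edges", {
  img <- bin_to_pixels(airway_intensity(0.2, pitch = 0.005), 0.05)
  counts <- expected_counts(img, 3.6e6, 0.05, 0.34)
  disp <- suppressWarnings(display_image(counts, 0.05))
  expect_true(all(disp >= 0 & disp <= 1))
  expect_equal(length(disp), length(counts))
  # unsharp masking increases local contrast across the fringe
  flat <- display_image(counts, 0.05, amount = 0)
  expect_gte(max(abs(diff(disp))), max(abs(diff(flat))) - 1e-12)
})
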