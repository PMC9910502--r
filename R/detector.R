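#' Photon-counting detector model
#'
#' Idealized pixelated photon-counting detector: absorption efficiency 1,
#' ideal scatter rejection, single-pixel point-spread function by default
#' (each pixel integrates the intensity over its own footprint only). The
#' reference configuration is 50-um pixels with incident fluence
#' 3.6e6 photons/mm^2 (monochromatic 60 keV at 0.1 mSv effective dose) or
#' 4e6 photons/mm^2 (filtered 120-kVp tungsten). The sensor thickness is
#' carried as metadata only.
#'
#' @param pixel_pitch Pixel pitch in mm (default 0.05).
#' @param sigma_det Gaussian pre-blur sigma in mm; 0 (default) is the
#'   single-pixel-PSF detector. Used for the ideal/non-ideal resolution
#'   studies.
#' @param fluence Incident photons/mm^2 on the patient (>= 0).
#' @param seed Integer seed for the Poisson noise generator.
#' @param sensor_thickness_mm Metadata only (default 0.75 mm CdTe).
#' @return Object of class `detector_model`.
#' @export
detector_model <- function(pixel_pitch = 0.05, sigma_det = 0,
                           fluence = 3.6e6, seed = 1L,
                           sensor_thickness_mm = 0.75) {
  stopifnot(pixel_pitch > 0, sigma_det >= 0, fluence >= 0)
  structure(list(pixel_pitch = pixel_pitch, sigma_det = sigma_det,
                 fluence = fluence, seed = as.integer(seed),
                 sensor_thickness_mm = sensor_thickness_mm),
            class = "detector_model")
}

#' @export
print.detector_model <- function(x, ...) {
  cat(sprintf("<detector_model> %g um pixels, sigma_det %g um, fluence %.3g /mm^2, seed %d\n",
              x$pixel_pitch * 1e3, x$sigma_det * 1e3, x$fluence, x$seed))
  invisible(x)
}

# normalized Gaussian kernel sampled on the grid, truncated at 8 sigma
gaussian_kernel <- function(sigma, pitch) {
  half <- max(1L, ceiling(8 * sigma / pitch))
  k <- stats::dnorm(seq(-half, half) * pitch, sd = sigma)
  k / sum(k)  # discrete normalization (exact DC preservation)
}

# 1D convolution with edge replication, same length as input
convolve_edge <- function(v, k) {
  half <- (length(k) - 1L) %/% 2L
  vp <- c(rep(v[1L], half), v, rep(v[length(v)], half))
  stats::filter(vp, k, method = "convolution", sides = 2L)[half + seq_along(v)]
}

#' Apply detector resolution blur
#'
#' Convolves the intensity with a normalized Gaussian of standard
#' deviation `sigma_det` expressed on the simulation grid (separable in
#' 2D); `sigma_det = 0` is the identity. Edge handling is replication,
#' consistent with the propagation padding. A `sigma_det` below the grid
#' pitch is under-resolved: the kernel is renormalized discretely and a
#' warning is raised.
#'
#' @param img An `intensity_image`.
#' @param sigma_det Blur sigma in mm (>= 0).
#' @return Blurred `intensity_image`.
#' @export
apply_detector_blur <- function(img, sigma_det) {
  stopifnot(inherits(img, "intensity_image"), sigma_det >= 0)
  if (sigma_det == 0) return(img)
  pitch <- img$grid$pitch
  if (sigma_det < pitch) {
    warning("sigma_det (", sigma_det, " mm) below grid pitch (", pitch,
            " mm); kernel is under-resolved and discretely normalized")
  }
  k <- gaussian_kernel(sigma_det, pitch)
  v <- img$values
  if (is.matrix(v)) {
    v <- t(apply(v, 1L, convolve_edge, k = k))
    v <- apply(v, 2L, convolve_edge, k = k)
  } else {
    v <- as.numeric(convolve_edge(v, k))
  }
  out <- img
  out$values <- v
  out
}

#' Bin the simulation grid into detector pixels
#'
#' Each pixel value is the mean of the simulation samples in its footprint
#' (area integration of the normalized intensity; the single-pixel PSF of
#' the photon-counting detector). The pixel pitch must be an integer
#' multiple of the simulation grid pitch.
#'
#' @param img An `intensity_image` on the fine simulation grid.
#' @param pitch Detector pixel pitch in mm.
#' @return A pixelated `intensity_image` whose grid pitch is `pitch`.
#' @export
bin_to_pixels <- function(img, pitch) {
  stopifnot(inherits(img, "intensity_image"), pitch > 0)
  r <- pitch / img$grid$pitch
  if (abs(r - round(r)) > 1e-9) {
    stop(sprintf("pixel pitch %g mm is not an integer multiple of the grid pitch %g mm; nearest valid pitch: %g mm",
                 pitch, img$grid$pitch, round(r) * img$grid$pitch))
  }
  r <- as.integer(round(r))
  block_centers <- function(x, np) {
    colMeans(matrix(x[seq_len(np * r)], nrow = r))
  }
  v <- img$values
  if (is.matrix(v)) {
    nxp <- ncol(v) %/% r; nyp <- nrow(v) %/% r
    v <- v[seq_len(nyp * r), seq_len(nxp * r), drop = FALSE]
    # mean over r x r blocks
    vb <- matrix(0, nyp, nxp)
    for (i in seq_len(r)) {
      for (j in seq_len(r)) {
        vb <- vb + v[seq(i, by = r, length.out = nyp),
                     seq(j, by = r, length.out = nxp)]
      }
    }
    vb <- vb / r^2
    g <- grid_spec(pitch, nxp * pitch, ny = nyp)
    g$n <- as.integer(nxp); g$ny <- as.integer(nyp)
    g$y <- block_centers(img$grid$y, nyp)
  } else {
    nxp <- length(v) %/% r
    vb <- colMeans(matrix(v[seq_len(nxp * r)], nrow = r))
    g <- grid_spec(pitch, nxp * pitch)
    g$n <- as.integer(nxp)
  }
  # pixel positions are the true footprint centers of the fine samples
  g$x <- block_centers(img$grid$x, g$n)
  # carry the normalization region across, scaled to pixel indices
  reg <- unique(pmax(1L, pmin(g$n, ceiling(img$normalization_region / r))))
  structure(list(values = vb, grid = g, normalization_region = reg),
            class = "intensity_image")
}

#' Expected photon counts per pixel
#'
#' `counts = fluence * pitch^2 * background_transmission * (I/I0)`.
#' Ideal scatter rejection: no additive background term. At the reference
#' fluence 3.6e6 /mm^2 and 50-um pixels a unity-transmission pixel expects
#' 9000 counts.
#'
#' @param img A pixelated `intensity_image`.
#' @param fluence Incident photons/mm^2 (>= 0).
#' @param pitch Pixel pitch in mm.
#' @param background_transmission Fraction of photons transmitted by the
#'   background ray (from the scene's own attenuation), in `[0, 1]`.
#' @return Numeric vector/matrix of expected counts.
#' @export
expected_counts <- function(img, fluence, pitch,
                            background_transmission = 1) {
  stopifnot(inherits(img, "intensity_image"), fluence >= 0, pitch > 0,
            background_transmission >= 0, background_transmission <= 1)
  fluence * pitch^2 * background_transmission * img$values
}

#' Poisson photon-counting noise
#'
#' Independent Poisson draws per pixel; the same seed reproduces the same
#' image bit-for-bit. The caller's RNG state is preserved.
#'
#' @param expected Non-negative expected counts (vector or matrix).
#' @param seed Integer seed.
#' @return Integer counts with the shape of `expected`.
#' @export
poisson_counts <- function(expected, seed) {
  if (any(expected < 0)) stop("expected counts must be >= 0")
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(as.integer(seed))
  counts <- stats::rpois(length(expected), lambda = as.vector(expected))
  if (is.matrix(expected)) {
    matrix(counts, nrow(expected), ncol(expected))
  } else {
    counts
  }
}

#' Full detector chain
#'
#' blur (optional) -> pixel binning -> expected counts -> Poisson noise.
#'
#' @param img Fine-grid `intensity_image`.
#' @param det A [detector_model()].
#' @param background_transmission Background-ray transmission fraction.
#' @return List with `pixels` (binned `intensity_image`), `expected`
#'   (counts) and `counts` (Poisson realization).
#' @export
detect_image <- function(img, det, background_transmission = 1) {
  stopifnot(inherits(det, "detector_model"))
  if (det$sigma_det > 0) img <- apply_detector_blur(img, det$sigma_det)
  px <- bin_to_pixels(img, det$pixel_pitch)
  exp_counts <- expected_counts(px, det$fluence, det$pixel_pitch,
                                background_transmission)
  list(pixels = px, expected = exp_counts,
       counts = poisson_counts(exp_counts, det$seed))
}

#' Generic display operator (not a vendor reproduction)
#'
#' Optional display conditioning for count images: unsharp masking
#' followed by percentile windowing to `[0, 1]`. Clinical radiography
#' post-processing pipelines are proprietary black boxes; this operator
#' is a generic stand-in for visual inspection only and reproduces no
#' vendor appearance.
#'
#' @param counts Numeric vector or matrix of pixel counts.
#' @param pitch Pixel pitch in mm.
#' @param amount Unsharp-mask strength (0 disables; default 0.5).
#' @param sigma Blur scale of the mask in mm (default 4 pixels).
#' @param window Lower/upper display percentiles (default `c(0.01, 0.99)`).
#' @return Numeric array in `[0, 1]` with the shape of `counts`.
#' @export
display_image <- function(counts, pitch, amount = 0.5, sigma = 4 * pitch,
                          window = c(0.01, 0.99)) {
  stopifnot(pitch > 0, amount >= 0, length(window) == 2L)
  v <- counts
  if (amount > 0) {
    img <- intensity_image_from_values(
      if (is.matrix(v)) v else as.numeric(v),
      {
        n <- if (is.matrix(v)) ncol(v) else length(v)
        g <- grid_spec(pitch, n * pitch,
                       ny = if (is.matrix(v)) nrow(v) else 1L)
        g$n <- as.integer(n)
        g$x <- pitch * (seq_len(n) - 1L - n / 2)
        g
      })
    low <- apply_detector_blur(img, sigma)$values
    v <- v + amount * (v - low)
  }
  q <- stats::quantile(v, window, names = FALSE)
  if (q[2L] <= q[1L]) q[2L] <- q[1L] + 1
  pmin(pmax((v - q[1L]) / (q[2L] - q[1L]), 0), 1)
}
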