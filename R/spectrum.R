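#' Photon wavelength from energy
#'
#' `lambda = hc / E` with `hc = 1.23984193 eV um`; 60 keV gives
#' 2.0664e-8 mm (0.0207 nm).
#'
#' @param energy_keV Photon energy in keV (> 0), vectorized.
#' @return Wavelength in mm.
#' @export
wavelength_from_energy <- function(energy_keV) {
  if (any(energy_keV <= 0)) stop("energy must be > 0 keV")
  hc_keV_mm <- 1.23984193e-3 * 1e-3  # eV um = 1e-3 keV * 1e-3 mm
  hc_keV_mm / energy_keV
}

#' Construct an X-ray spectrum
#'
#' A spectrum is a set of energy bins with relative fluence. The class is
#' `xray_spectrum` (avoiding a clash with [stats::spectrum()]).
#'
#' @param energy_keV Strictly increasing bin energies, keV.
#' @param fluence Relative fluence per bin, >= 0 with positive total.
#' @param kind `"monochromatic"` or `"tabulated"`.
#' @return Object of class `xray_spectrum`.
#' @export
xray_spectrum <- function(energy_keV, fluence, kind = "tabulated") {
  stopifnot(length(energy_keV) == length(fluence), length(energy_keV) >= 1L)
  if (any(energy_keV <= 0)) stop("bin energies must be > 0 keV")
  if (length(energy_keV) > 1L && any(diff(energy_keV) <= 0)) {
    stop("bin energies must be strictly increasing")
  }
  if (any(fluence < 0)) stop("relative fluence must be >= 0")
  if (sum(fluence) <= 0) stop("total relative fluence must be > 0")
  kind <- match.arg(kind, c("monochromatic", "tabulated"))
  if (kind == "monochromatic" && length(energy_keV) != 1L) {
    stop("a monochromatic spectrum has exactly one bin")
  }
  structure(list(energy_keV = as.numeric(energy_keV),
                 fluence = as.numeric(fluence), kind = kind),
            class = "xray_spectrum")
}

#' Monochromatic spectrum
#'
#' @param energy_keV Photon energy in keV (> 0).
#' @return Single-bin `xray_spectrum` with fluence 1.
#' @export
monochromatic <- function(energy_keV) {
  xray_spectrum(energy_keV, 1, kind = "monochromatic")
}

#' @export
print.xray_spectrum <- function(x, ...) {
  cat(sprintf("<xray_spectrum> %s, %d bin(s), mean energy %.3g keV\n",
              x$kind, length(x$energy_keV), mean_energy(x)))
  invisible(x)
}

#' Read a spectrum from a two-column delimited text file
#'
#' Columns: energy (keV) and relative fluence; `#` starts a comment.
#'
#' @param path File path.
#' @return An `xray_spectrum` (monochromatic when the file has one row).
#' @export
read_spectrum <- function(path) {
  d <- utils::read.table(path, header = FALSE, sep = "", comment.char = "#")
  if (ncol(d) < 2L) stop("spectrum file ", path, ": need two columns (keV, fluence)")
  xray_spectrum(d[[1L]], d[[2L]],
                kind = if (nrow(d) == 1L) "monochromatic" else "tabulated")
}

#' Write a spectrum to a two-column delimited text file
#'
#' @param spec An `xray_spectrum`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spec, path) {
  stopifnot(inherits(spec, "xray_spectrum"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# pbisim spectrum: energy_keV relative_fluence", con)
  utils::write.table(data.frame(spec$energy_keV, spec$fluence), con,
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Bundled filtered 120-kVp tungsten spectrum
#'
#' Loads the package's tabulated 120-kVp tungsten-anode spectrum (1-keV
#' bins, bremsstrahlung continuum plus K lines, 2.5 mm Al inherent
#' filtration) and applies the standard 4.3-mm added aluminum filtration,
#' yielding the conventional chest-radiography beam whose mean energy is
#' close to 60 keV. The table is a synthetic reference spectrum generated
#' from a textbook tube model, not a measured tube spectrum.
#'
#' @param added_al_mm Added aluminum filtration in mm (default 4.3).
#' @param table Material table providing aluminum (default built-ins).
#' @return An `xray_spectrum`.
#' @export
tungsten_spectrum <- function(added_al_mm = 4.3, table = builtin_materials()) {
  path <- system.file("extdata", "spectrum_w120kvp.tsv", package = "pbisim",
                      mustWork = TRUE)
  spec <- read_spectrum(path)
  if (added_al_mm > 0) {
    spec <- filter_spectrum(spec, get_material(table, "aluminum"), added_al_mm)
  }
  spec
}

#' Filter a spectrum through a material slab
#'
#' Per-bin Beer-Lambert attenuation: fluence is multiplied by
#' `exp(-mu(E) * thickness)`. Filtering a bremsstrahlung-like spectrum with
#' aluminum hardens the beam (mean energy increases).
#'
#' @param spec An `xray_spectrum`.
#' @param m A `material`.
#' @param thickness Slab thickness in mm (>= 0).
#' @return The filtered `xray_spectrum`.
#' @export
filter_spectrum <- function(spec, m, thickness) {
  stopifnot(inherits(spec, "xray_spectrum"), inherits(m, "material"),
            thickness >= 0)
  if (thickness == 0) return(spec)
  if (nrow(m$mu_table) == 0L) {
    stop("material '", m$name, "' has no attenuation table")
  }
  rng <- range(m$mu_table[, 1L])
  if (min(spec$energy_keV) < rng[1L] / 2 || max(spec$energy_keV) > rng[2L] * 2) {
    stop("mu table of '", m$name, "' does not cover the spectrum energy range")
  }
  f <- spec$fluence * exp(-mu_at(m, spec$energy_keV) * thickness)
  xray_spectrum(spec$energy_keV, f, kind = spec$kind)
}

#' Fluence-weighted mean energy of a spectrum
#'
#' @param spec An `xray_spectrum`.
#' @return Mean energy in keV.
#' @export
mean_energy <- function(spec) {
  stopifnot(inherits(spec, "xray_spectrum"))
  sum(spec$energy_keV * spec$fluence) / sum(spec$fluence)
}

#' Polychromatic intensity image of a scene
#'
#' Forms the detected image of a scene under an arbitrary spectrum as an
#' incoherent, detected-fluence-weighted sum of per-bin intensity images:
#' each bin is propagated coherently at its own wavelength through the
#' monochromatic chain, and the resulting I/I0 images are averaged with
#' weights fluence x background transmission at that energy (each detected
#' photon counts once, as in a photon-counting detector; set
#' `energy_weighting = TRUE` for energy-integrating weights). At z = 0 this
#' reduces to polychromatic Beer-Lambert transmission with no fringes: the
#' conventional-radiography setting.
#'
#' Per-bin coherent propagation with incoherent summation at z > 0 is
#' physically standard but the polychromatic phase-contrast combination is
#' marked experimental: the reference simulations propagate
#' monochromatically.
#'
#' @param scene A [phantom_scene()].
#' @param spec An `xray_spectrum`.
#' @param z Propagation distance in mm (>= 0).
#' @param grid A [grid_spec()]; sampling is checked at the shortest
#'   wavelength (highest energy) in the spectrum.
#' @param table A `material_table` (default built-ins).
#' @param energy_weighting Use energy-integrating detector weights.
#' @param normalization_region Passed to [intensity_image()]; default the
#'   outer 10% margin on each side.
#' @return An `intensity_image` (I/I0), plus attributes `weights` (the
#'   detected weights used) and `background_transmission` (the
#'   fluence-weighted background transmission, used for absolute counts).
#' @export
polychromatic_image <- function(scene, spec, z, grid,
                                table = builtin_materials(),
                                energy_weighting = FALSE,
                                normalization_region = NULL) {
  stopifnot(inherits(scene, "phantom_scene"), inherits(spec, "xray_spectrum"),
            z >= 0, inherits(grid, "grid_spec"))
  lam_min <- wavelength_from_energy(max(spec$energy_keV))
  chk <- check_sampling(grid$pitch, lam_min, z)
  if (!chk$pass) {
    stop(sprintf("grid pitch %.3g mm violates the sampling bound %.3g mm at the highest bin energy",
                 grid$pitch, chk$bound_mm))
  }
  tmap <- project_scene(scene, grid)
  bg <- get_material(table, scene$background_material)

  acc <- NULL
  wts <- numeric(length(spec$energy_keV))
  for (k in seq_along(spec$energy_keV)) {
    E <- spec$energy_keV[k]
    wf <- transmission_function(tmap, table, E)
    if (z > 0) wf <- fresnel_propagate(wf, propagation_plan(z))
    img <- intensity_image(wf, normalization_region)
    trans_bg <- exp(-mu_at(bg, E) * scene$background_thickness)
    w <- spec$fluence[k] * trans_bg * (if (energy_weighting) E else 1)
    wts[k] <- w
    acc <- if (is.null(acc)) w * img$values else acc + w * img$values
  }
  out <- intensity_image_from_values(acc / sum(wts), grid,
                                     normalization_region)
  attr(out, "weights") <- wts
  attr(out, "background_transmission") <-
    sum(spec$fluence * exp(-mu_at(bg, spec$energy_keV) * scene$background_thickness)) /
    sum(spec$fluence)
  out
}
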