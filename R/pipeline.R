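#' Simulation run configuration
#'
#' Bundles and validates everything one radiography run needs. Three modes
#' mirror the standard virtual-trial settings:
#' * `"phase_contrast"`: monochromatic beam, z > 0 (polychromatic
#'   propagation only behind `allow_polychromatic`, experimental);
#' * `"conventional"`: filtered tungsten spectrum, z forced to 0;
#' * `"control"`: monochromatic beam, z forced to 0.
#'
#' Defaults reproduce the reference setting: 60 keV, z = 12 m, 50-um
#' pixels, fluence 3.6e6 photons/mm^2.
#'
#' @param mode One of `"phase_contrast"`, `"conventional"`, `"control"`.
#' @param scene List describing the scene: `type = "airway"` (fields
#'   `wall_thickness`, optional `lumen_diameter`, `background_thickness`,
#'   `extent`) or `type = "nodule"` (fields `diameter`, optional `extent`,
#'   `background_thickness`, `two_d`).
#' @param spectrum List: `kind = "monochromatic"` with `energy_keV`,
#'   `kind = "tungsten"` (bundled filtered 120-kVp table, optional
#'   `added_al_mm`), or `kind = "file"` with `path`.
#' @param geometry List with `z_mm` (propagation distance).
#' @param grid List with `pitch_mm`, optional `extent_mm` (default scene
#'   extent), `ny`.
#' @param detector List with `pixel_pitch_mm`, `sigma_det_mm`,
#'   `fluence_per_mm2`, `seed`.
#' @param output List with optional `dir`; when set, [run_simulation()]
#'   writes image/profile/report files there.
#' @param allow_polychromatic Permit z > 0 with a polychromatic spectrum.
#' @return Object of class `run_config`.
#' @export
run_config <- function(mode = "phase_contrast",
                       scene = list(type = "airway", wall_thickness = 0.2),
                       spectrum = list(kind = "monochromatic", energy_keV = 60),
                       geometry = list(z_mm = 12000),
                       grid = list(pitch_mm = 0.005),
                       detector = list(pixel_pitch_mm = 0.05,
                                       sigma_det_mm = 0,
                                       fluence_per_mm2 = 3.6e6, seed = 1L),
                       output = list(),
                       allow_polychromatic = FALSE) {
  mode <- match.arg(mode, c("phase_contrast", "conventional", "control"))
  if (mode == "conventional") {
    geometry$z_mm <- 0
    if (is.null(spectrum$kind) || spectrum$kind == "monochromatic") {
      spectrum <- list(kind = "tungsten")
    }
  } else if (mode == "control") {
    geometry$z_mm <- 0
    if (!identical(spectrum$kind, "monochromatic")) {
      spectrum <- list(kind = "monochromatic",
                       energy_keV = spectrum$energy_keV %||% 60)
    }
  } else {
    if (is.null(geometry$z_mm) || geometry$z_mm <= 0) {
      stop("phase_contrast mode requires z_mm > 0")
    }
    if (!identical(spectrum$kind %||% "monochromatic", "monochromatic") &&
        !allow_polychromatic) {
      stop("phase_contrast mode is monochromatic unless allow_polychromatic = TRUE (experimental)")
    }
  }
  stopifnot(is.list(scene), !is.null(scene$type))
  scene$type <- match.arg(scene$type, c("airway", "nodule"))
  grid$pitch_mm <- grid$pitch_mm %||% 0.005
  detector$pixel_pitch_mm <- detector$pixel_pitch_mm %||% 0.05
  detector$sigma_det_mm <- detector$sigma_det_mm %||% 0
  detector$fluence_per_mm2 <- detector$fluence_per_mm2 %||% 3.6e6
  detector$seed <- as.integer(detector$seed %||% 1L)
  structure(list(mode = mode, scene = scene, spectrum = spectrum,
                 geometry = geometry, grid = grid, detector = detector,
                 output = output,
                 allow_polychromatic = allow_polychromatic),
            class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("<run_config> mode %s, scene %s, z = %g m, pitch %g um, pixels %g um\n",
              x$mode, x$scene$type, x$geometry$z_mm / 1e3,
              x$grid$pitch_mm * 1e3, x$detector$pixel_pitch_mm * 1e3))
  invisible(x)
}

# materialize scene/spectrum from a config
build_scene <- function(sc) {
  if (sc$type == "airway") {
    airway_scene(wall_thickness = sc$wall_thickness %||% 0.2,
                 lumen_diameter = sc$lumen_diameter %||% 2,
                 background_thickness = sc$background_thickness %||% 100,
                 extent = sc$extent %||% 8)
  } else {
    nodule_scene(diameter = sc$diameter %||% 8,
                 extent = sc$extent %||% (4 * ceiling((sc$diameter %||% 8) / 2) + 8),
                 background_thickness = sc$background_thickness %||% 100)
  }
}

build_spectrum <- function(sp) {
  kind <- sp$kind %||% "monochromatic"
  switch(kind,
         monochromatic = monochromatic(sp$energy_keV %||% 60),
         tungsten = tungsten_spectrum(added_al_mm = sp$added_al_mm %||% 4.3),
         file = read_spectrum(sp$path),
         stop("unknown spectrum kind '", kind, "'"))
}

#' Named run fixtures
#'
#' Returns a complete, runnable [run_config()] for the canonical
#' scenarios:
#' * `"isolated_airway"`: 2-mm lumen, `wall_thickness` (default 0.2 mm)
#'   muscle wall in parenchyma; 60 keV, z = 12 m, 50-um pixels.
#' * `"airway_sweep"`: list of three configs with walls 0.1/0.2/0.4 mm.
#' * `"nodule_roi"`: 2D parenchyma ROI with a muscle-density sphere
#'   (`diameter` 6--20 mm, default 8), conventional-geometry defaults.
#'
#' @param name Fixture name.
#' @param ... Overrides (`wall_thickness`, `diameter`, `z_mm`,
#'   `pitch_mm`, `seed`, ...).
#' @return A `run_config`, or a list of them for `"airway_sweep"`.
#' @export
build_fixture <- function(name, ...) {
  name <- match.arg(name, c("isolated_airway", "airway_sweep", "nodule_roi"))
  dots <- list(...)
  z <- dots$z_mm %||% 12000
  pitch <- dots$pitch_mm %||% 0.005
  seed <- dots$seed %||% 1L
  if (name == "airway_sweep") {
    return(lapply(c(0.1, 0.2, 0.4), function(d) {
      build_fixture("isolated_airway", wall_thickness = d, z_mm = z,
                    pitch_mm = pitch, seed = seed)
    }))
  }
  if (name == "isolated_airway") {
    run_config(
      mode = "phase_contrast",
      scene = list(type = "airway",
                   wall_thickness = dots$wall_thickness %||% 0.2),
      spectrum = list(kind = "monochromatic",
                      energy_keV = dots$energy_keV %||% 60),
      geometry = list(z_mm = z),
      grid = list(pitch_mm = pitch),
      detector = list(pixel_pitch_mm = dots$pixel_pitch_mm %||% 0.05,
                      sigma_det_mm = dots$sigma_det_mm %||% 0,
                      fluence_per_mm2 = dots$fluence_per_mm2 %||% 3.6e6,
                      seed = seed)
    )
  } else {
    diameter <- dots$diameter %||% 8
    run_config(
      mode = dots$mode %||% "phase_contrast",
      scene = list(type = "nodule", diameter = diameter,
                   extent = dots$extent %||% (diameter + 4), two_d = TRUE),
      spectrum = list(kind = "monochromatic",
                      energy_keV = dots$energy_keV %||% 60),
      geometry = list(z_mm = z),
      grid = list(pitch_mm = dots$pitch_mm %||% 0.005),
      detector = list(pixel_pitch_mm = dots$pixel_pitch_mm %||% 0.05,
                      sigma_det_mm = dots$sigma_det_mm %||% 0,
                      fluence_per_mm2 = dots$fluence_per_mm2 %||% 3.6e6,
                      seed = seed)
    )
  }
}

#' Run a full radiography simulation
#'
#' Executes the pipeline project -> transmit -> propagate -> blur -> bin
#' -> counts -> metrics for one configuration. With `output$dir` set,
#' writes the pixel image (16-bit TIFF + scale sidecar), fine and
#' pixelated profiles, the metrics report and a run report echoing every
#' parameter, package version and seed; outputs are removed again if a
#' later stage fails. Identical config + seed gives bit-identical results.
#'
#' @param config A [run_config()] (or plain list coerced through it).
#' @param table A `material_table` (default built-ins).
#' @return Object of class `pbi_run`: fields `config`, `tmap`, `image`
#'   (fine-grid `intensity_image`), `detected` (from [detect_image()]),
#'   `profile` (fine-grid `intensity_profile`), `pixel_profile`,
#'   `metrics`, `background_transmission`, `report`.
#' @export
run_simulation <- function(config, table = builtin_materials()) {
  if (!inherits(config, "run_config")) config <- do.call(run_config, config)
  stage <- "setup"
  written <- character(0)
  out_dir <- config$output$dir %||% NULL
  on_fail <- function(e) {
    for (f in written) unlink(c(f, paste0(f, ".scale.txt")))
    stop("stage '", stage, "': ", conditionMessage(e), call. = FALSE)
  }
  tryCatch({
    stage <- "scene"
    scene <- build_scene(config$scene)
    two_d <- isTRUE(config$scene$two_d)
    grid <- grid_spec(config$grid$pitch_mm,
                      config$grid$extent_mm %||% scene$extent,
                      ny = if (two_d) (config$grid$ny %||%
                                         round(scene$extent / config$grid$pitch_mm))
                           else 1L)
    spec <- build_spectrum(config$spectrum)
    z <- config$geometry$z_mm

    stage <- "sampling check"
    lam_min <- wavelength_from_energy(max(spec$energy_keV))
    chk <- check_sampling(grid$pitch, lam_min, z)
    if (!chk$pass) {
      stop(sprintf("grid pitch %.3g mm exceeds the bound %.3g mm at z = %g mm",
                   grid$pitch, chk$bound_mm, z))
    }

    stage <- "projection"
    tmap <- project_scene(scene, grid)

    stage <- "wave optics"
    if (spec$kind == "monochromatic") {
      wf <- transmission_function(tmap, table, spec$energy_keV)
      if (z > 0) wf <- fresnel_propagate(wf, propagation_plan(z))
      img <- intensity_image(wf)
      bg <- get_material(table, scene$background_material)
      bg_trans <- exp(-mu_at(bg, spec$energy_keV) * scene$background_thickness)
    } else {
      img <- polychromatic_image(scene, spec, z, grid, table = table)
      bg_trans <- attr(img, "background_transmission")
    }

    stage <- "detector"
    det <- detector_model(pixel_pitch = config$detector$pixel_pitch_mm,
                          sigma_det = config$detector$sigma_det_mm,
                          fluence = config$detector$fluence_per_mm2,
                          seed = config$detector$seed)
    detected <- detect_image(img, det, background_transmission = bg_trans)

    stage <- "metrics"
    profile <- extract_profile(img)
    pixel_profile <- extract_profile(detected$pixels)
    wall_true <- if (config$scene$type == "airway") {
      config$scene$wall_thickness %||% 0.2
    } else NA_real_
    metrics <- if (config$scene$type == "airway") {
      measure_profile(profile, wall_thickness = wall_true)
    } else {
      list(fringe_visibility = fringe_visibility(profile))
    }

    stage <- "report"
    report <- list(
      package = "pbisim",
      version = as.character(utils::packageVersion("pbisim")),
      mode = config$mode,
      scene = config$scene,
      spectrum_kind = spec$kind,
      spectrum_mean_energy_keV = mean_energy(spec),
      z_mm = z,
      grid_pitch_mm = grid$pitch,
      grid_n = grid$n,
      pixel_pitch_mm = det$pixel_pitch,
      sigma_det_mm = det$sigma_det,
      fluence_per_mm2 = det$fluence,
      seed = det$seed,
      background_transmission = bg_trans,
      metrics = metrics
    )

    if (!is.null(out_dir)) {
      stage <- "output"
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      f <- file.path(out_dir, "counts.tif")
      write_image(detected$counts, f); written <- c(written, f)
      f <- file.path(out_dir, "profile_fine.tsv")
      write_profile(profile, f); written <- c(written, f)
      f <- file.path(out_dir, "profile_pixels.tsv")
      write_profile(pixel_profile, f); written <- c(written, f)
      f <- file.path(out_dir, "metrics.json")
      write_report(metrics, f); written <- c(written, f)
      f <- file.path(out_dir, "run_report.json")
      write_report(report, f); written <- c(written, f)
    }

    structure(list(config = config, tmap = tmap, image = img,
                   detected = detected, profile = profile,
                   pixel_profile = pixel_profile, metrics = metrics,
                   background_transmission = bg_trans, report = report),
              class = "pbi_run")
  }, error = on_fail)
}

#' @export
print.pbi_run <- function(x, ...) {
  cat(sprintf("<pbi_run> %s, z = %g m, %d fine samples -> %d pixels\n",
              x$config$mode, x$config$geometry$z_mm / 1e3,
              x$image$grid$n, x$detected$pixels$grid$n))
  if (!is.null(x$metrics$fringe_visibility)) {
    cat(sprintf("  fringe visibility %.4g\n", x$metrics$fringe_visibility))
  }
  if (!is.null(x$metrics$wall_estimate_mm) &&
      !is.na(x$metrics$wall_estimate_mm)) {
    cat(sprintf("  wall estimate %.4g mm (true %.4g mm)\n",
                x$metrics$wall_estimate_mm, x$metrics$wall_true_mm))
  }
  invisible(x)
}
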