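# shared fixtures for the wave-optics tests

keV60 <- 60
lam60 <- wavelength_from_energy(60)  # 2.0664e-8 mm

# propagated intensity of the canonical isolated-airway scene
airway_intensity <- function(wall_thickness, z = 12000, pitch = 0.0025,
                             energy_keV = 60, extent = 8) {
  tm <- project_scene(airway_scene(wall_thickness, extent = extent),
                      grid_spec(pitch, extent))
  wf <- transmission_function(tm, builtin_materials(), energy_keV)
  if (z > 0) wf <- fresnel_propagate(wf, propagation_plan(z))
  intensity_image(wf)
}

# smooth compact perturbation on a unit background: constant near the window
# edges, so propagation invariants are free of boundary effects
compact_test_field <- function(grid, amp_depth = 0.2, phase_amp = 0.4,
                               sigma = 0.04) {
  u <- (1 - amp_depth * exp(-grid$x^2 / (2 * sigma^2))) *
    exp(1i * phase_amp * exp(-grid$x^2 / (2 * (1.2 * sigma)^2)))
  wavefront(u, grid, lam60)
}

# windowed sub-profile helper
profile_window <- function(p, lo, hi) {
  sel <- which(p$x > lo & p$x < hi)
  structure(list(x = p$x[sel], values = p$values[sel], pitch = p$pitch,
                 normalization_region = NULL),
            class = "intensity_profile")
}
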