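# pbisim

A wave-optics simulator for **propagation-based phase-contrast (PBI)
X-ray radiography** of soft-tissue phantoms, written for imaging
physicists exploring whether near-field diffraction can make sub-2-mm
airway walls — invisible in attenuation-only chest radiography — directly
measurable at clinical X-ray energies.

In PBI, a free-space distance *z* between patient and detector lets
Fresnel diffraction convert phase gradients into intensity fringes at
tissue interfaces. `pbisim` implements the full chain for analytic
phantoms (airway cylinders, nodule spheres, background slabs):

1. **Projection** — exact chord integration into per-material thickness
   maps *t<sub>m</sub>(x)* at micrometre pitch, with per-ray thickness
   conservation;
2. **Transmission** — φ = −(2π/λ) Σ<sub>m</sub> δ<sub>m</sub> t<sub>m</sub>
   and amplitude exp(−½ Σ<sub>m</sub> μ<sub>m</sub> t<sub>m</sub>)
   (projection approximation, n = 1 − δ);
3. **Fresnel propagation** — spectral transfer function
   H(ν) = exp(−iπλz|ν|²) on an edge-padded FFT grid, guarded by the
   sampling bound x<sub>s</sub> ≤ √(λz)/2, validated against an analytic
   Gaussian solution and direct quadrature of the Fresnel integral;
4. **Photon-counting detection** — Gaussian resolution blur, single-pixel
   PSF binning (50-µm pixels), expected counts
   Φ·p²·T<sub>bg</sub>·(I/I₀) and seeded Poisson noise, with ideal scatter
   rejection;
5. **Metrics** — edge-enhancement width, fringe visibility, and airway
   wall-thickness estimation from fringe positions;
6. **System design** — σ<sub>FZ</sub> = √(λz), transverse coherence
   l<sub>t</sub> ≈ Rλ/σ<sub>src</sub>, the source requirement
   R/σ<sub>src</sub> ≥ √(z/(2λ)), magnification M = (R+d)/R and effective
   distance d/M.

Monochromatic (60 keV) and filtered 120-kVp tungsten spectra are
supported; the three standard settings (phase contrast at z > 0,
conventional tungsten at z = 0, monochromatic control at z = 0) are
built-in run modes.

## Worked example

Simulate the canonical isolated small airway — 2-mm air lumen with a
0.2-mm muscle wall in a 100-mm lung-parenchyma slab — at 60 keV and
z = 12 m on a 5-µm grid, detected with 50-µm photon-counting pixels at
3.6·10⁶ photons/mm²:

```r
library(pbisim)
run <- run_simulation(build_fixture("isolated_airway"))
print(run)
#> <pbi_run> phase_contrast, z = 12 m, 1600 fine samples -> 160 pixels
#>   fringe visibility 0.9926
#>   wall estimate 0.2046 mm (true 0.2 mm)
```

Each air/wall interface carries a paired intensity overshoot/undershoot
(the edge enhancement); its width on the fine grid is a couple of
Fresnel-zone widths (σ_FZ ≈ 16 µm here), and after binning to 50-µm
pixels it is detector-limited at two pixels (100 µm;
`edge_width_detector_limited()` reports the median over sub-pixel
registrations). The wall estimate (0.2046 mm) recovers the true 0.2-mm
wall from the fringe positions; at 50-µm pixels the recovery error is
bounded by the detector resolution, which is the clinically relevant
statement.

The design calculus sizes a coherent system for z_eff = 6 m:

```r
sol <- solve_patient_detector_distance(R = 20000, z_eff = 6000)  # mm
system_report(geometry_design(60, R = 20000, dpd = sol$dpd, sigma_src = 0.05))
#> <design_report>
#>   energy        60 keV (lambda = 2.066e-08 mm)
#>   geometry      R = 20 m, dpd = 8.57 m, total = 28.6 m, M = 1.43
#>   z_eff         6 m -> sigma_FZ = 11.1 um, sampling bound = 5.57 um
#>   coherence     l_t = 8.27 um, criterion l_t >= sigma_FZ/2: pass (margin 1.48)
#>   detector      sigma_det = 100 um -> non-ideal
```

i.e. a 50-µm source needs R ≈ 20 m, giving a patient-to-detector distance
of ≈ 8.6 m (M ≈ 1.43) and a total system under 30 m.

A thin command-line front end (`inst/cli/pbisim.R`) exposes `simulate`,
`design`, `fixture` and `metrics` subcommands over YAML run configs;
outputs are 16-bit TIFF count images (with a lossless scale sidecar),
two-column profiles, and JSON metric/run reports that echo every
parameter and seed.

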