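---
title: "Wave-optics simulation of propagation-based phase-contrast radiography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wave-optics simulation of propagation-based phase-contrast radiography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pbisim)
```

## The model

Propagation-based phase-contrast imaging (PBI) exploits free-space
propagation between object and detector: Fresnel (near-field) diffraction
converts transverse gradients of the X-ray phase into intensity fringes
that decorate material interfaces. `pbisim` simulates this chain for
soft-tissue phantoms — most importantly the isolated small airway, an
air-filled cylinder of lumen diameter $D$ with a muscle-like wall of
thickness $d$ embedded in lung parenchyma — and implements the design
algebra that sizes a clinical PBI system.

The chain is the standard scalar wave-optics model under the projection
approximation:

1. **Projection.** Analytic chord integration turns a scene into
   per-material thickness maps $t_m(x)$ on a micrometre-pitch grid.
   Objects displace the homogeneous background slab along their chord, so
   $\sum_m t_m(x)$ equals the slab thickness for every ray (a machine-precision
   invariant of the projector).
2. **Transmission.** For refractive index $n = 1 - \delta$ the exit
   wavefront of a unit plane wave is
   $u_0(x) = \exp\!\big(-\tfrac12\sum_m \mu_m t_m\big)\,
   \exp\!\big(-i\tfrac{2\pi}{\lambda}\sum_m \delta_m t_m\big)$,
   i.e. the phase is $\varphi = -\frac{2\pi}{\lambda}\int \delta\,dz$ and the
   amplitude is Beer–Lambert.
3. **Propagation.** Single-distance Fresnel propagation by the spectral
   transfer function $H(\nu) = \exp(-i\pi\lambda z |\nu|^2)$ (the global
   $e^{ikz}$ phase is dropped), evaluated by FFT on an
   edge-replication-padded grid (factor $\ge 2$) and cropped back.
   The sign pair ($\varphi$ negative, $H$ with negative exponent) is
   self-consistent and validated against direct quadrature of the Fresnel
   integral; mixing conventions flips the fringe asymmetry.
4. **Detection.** An idealized photon-counting detector: optional Gaussian
   resolution blur $\sigma_{det}$, area-integration binning into pixels
   (single-pixel PSF), expected counts
   $N = \Phi\,p^2\,T_{bg}\,(I/I_0)$ at incident fluence $\Phi$, pixel
   pitch $p$ and background transmission $T_{bg}$, then independent
   Poisson draws. Scatter rejection is ideal (no additive background) and
   absorption efficiency is 1; the 0.75-mm CdTe sensor thickness is
   metadata only.

The design module collects the system calculus: Fresnel-zone width
$\sigma_{FZ} = \sqrt{\lambda z}$, wavefront-sampling bound
$x_s \le \sigma_{FZ}/2$, transverse coherence $l_t \approx R\lambda/\sigma_{src}$,
magnification $M = (R + d_{pd})/R$ with effective distance $z_{eff} = d_{pd}/M$,
and the source requirement $R/\sigma_{src} \ge \sqrt{z/(2\lambda)}$.

### A note on the coherence criterion

The ratio $R/\sigma_{src} \ge \sqrt{z/(2\lambda)}$ (which reproduces the
reference numbers $3.8\times10^5$ at $z = 6$ m, $R \ge 20$ m for a 50-µm
source, $d_{pd}\approx 8.6$ m, $M \approx 1.43$, total length under 30 m)
is algebraically equivalent to $l_t \ge \sigma_{FZ}/\sqrt{2}$, not to the
often-quoted verbal criterion $l_t \ge \sigma_{FZ}/2$ — the two differ by
$\sqrt2$. Both conventions circulate in the PBI design literature.
`required_ratio()` and `minimal_R()` implement the ratio form;
`system_report()` reports pass/fail against the looser $\sigma_{FZ}/2$
form. Property tests check the exact $\sqrt2$-corrected equivalence.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| energy $E$ | 60 | keV | matches the mean of a filtered 120-kVp tungsten beam, so phase-contrast and conventional images share patient transmission |
| $\delta$ at 60 keV | $6.91\cdot10^{-11}$ (air), $6.66\cdot10^{-8}$ (muscle), $3.37\cdot10^{-8}$ (parenchyma) | – | reference soft-tissue decrements; interpolated $\propto 1/E^2$ (valid away from edges) |
| densities | 0.0012 / 1.05 / 0.53 | g/cm³ | air, muscle, parenchyma |
| $z$ | 12 000 | mm | the upper end of the 2–12 m sweep, strongest edge enhancement |
| grid pitch $x_s$ | 0.0025 | mm | below the bound $\sqrt{\lambda z}/2 \approx 7.9$ µm at 12 m (≈3.2 µm at 2 m) |
| lumen $D$, wall $d$ | 2, 0.1–0.4 | mm | the small-airway wall-thickening sweep |
| background slab | 100 | mm | parenchyma path length; intensities are normalized to the parenchyma-only region, so results depend on it only through attenuation/statistics |
| pixel pitch | 0.05 | mm | photon-counting detector, single-pixel PSF |
| fluence | $3.6\cdot10^{6}$ (60 keV), $4\cdot10^{6}$ (tungsten) | photons/mm² | 0.1-mSv dose calibration carried as given constants |

Attenuation coefficients $\mu$ are not part of the phase physics and no
reference values accompany the $\delta$ set; the built-in table carries
$\mu/\rho$ from the standard compilations (air, muscle, lung parenchyma,
aluminum) to 3–4 significant figures, user-overridable through
`load_material_table()`. CdTe is not tabulated because detector
efficiency is fixed at 1, so sensor attenuation never enters the
computation.

The bundled 120-kVp tungsten table
(`inst/extdata/spectrum_w120kvp.tsv`) is a *synthetic reference
spectrum*: a Kramers bremsstrahlung continuum with tungsten
K-characteristic lines, pre-hardened by 2.5 mm Al inherent filtration.
After the standard 4.3-mm added aluminum (`tungsten_spectrum()`) its mean
energy is 59.3 keV; its only roles are that mean (~60 keV) and the
fringe-free $z = 0$ attenuation image, both tolerance-checked.

## What the phantom generator does and does not emulate

Scenes are analytic: cylinders (airways), spheres (nodules) and a
homogeneous background slab, projected by exact chord formulas (a
voxel-grid ray-sum projector exists for user phantoms, without any
edge-preserving upsampling). This reproduces the isolated-object
scenarios that the quantitative claims rest on — fringe formation,
detector-limited edge width, wall-thickness recovery — at desk scale in
seconds. It deliberately does **not** emulate anatomical realism:
parenchyma texture, vasculature, overlapping structures, alveolar-scale
speckle, or full-thorax fields. Passing tests therefore demonstrate the
physics and the measurement operators, not reader-level realism of whole
radiographs; contrast in real lungs sits on a structured background that
this package represents as homogeneous.

1D profile mode (a cylinder cross-section) is the default for airway
studies; 2D mode exists for nodule regions of interest and is capped at
desk scale by the same sampling guard.

## Numerical choices

* **Grid convention.** Samples at $x_i = x_s (i - 1 - N/2)$, $N$ forced
  even; symmetric up to the one unpaired leftmost sample. Pixel binning
  positions pixels at the true mean of their fine-sample footprints.
* **Padding.** Edge replication, factor ≥ 2, FFT sizes rounded up to even
  2–3–5-smooth numbers; cropping back after the transform. Replication
  suits the non-periodic slab borders; wrap-around and truncation
  artifacts are quantified by the Parseval, semigroup and unitarity tests
  (all pass at $10^{-6}$ or better for perturbations that stay inside the
  window).
* **Precision.** Everything is double precision (R's native complex);
  tolerance targets assume it.
* **Sampling guard.** `fresnel_propagate()` refuses grids with
  $x_s > \sqrt{\lambda z}/2$ rather than degrading silently; z = 0 is an
  exact identity; back-propagation requires an explicit inverse flag.
* **Oracles.** Two independent cross-checks validate the propagator: the
  closed-form Fresnel propagation of a Gaussian (exact paraxial solution;
  agreement $10^{-9}$) and direct $O(N^2)$ quadrature of the Fresnel
  integral. The sampled chirp kernel of the direct integral is only
  Nyquist-adequate for $z \gtrsim N x_s^2/\lambda$, so oracle comparisons
  run near that critical distance, and the quadrature tapers the padded
  margin with a raised cosine to suppress truncation ringing. Away from
  that regime the spectral method remains valid while the quadrature does
  not — the direct integral is an oracle, never the production path.
* **Degenerate inputs.** Vacuum-like materials return $\mu = 0$; empty
  scenes project to a pure slab; flat profiles give zero visibility and
  no-estimate flags; Poisson draws restore the caller's RNG state.

## Measurement operators

The fringe metrics operationalize what a reader does with calipers:

* `edge_width()` measures one interface per analysis window against
  *side-local* baselines (the plateau level at each window end), because
  an interface generally separates two transmission plateaus and the
  fringe rides on the attenuation step. A fringe is detected only when
  the overshoot clears the higher plateau and the undershoot undercuts
  the lower one by 3 baseline standard deviations (so a $z=0$ attenuation
  step is flagged no-fringe); the width is the span of the contiguous
  excursions above 25% of the peak deviation. Both thresholds are
  configurable. On the fine grid this width is a couple of Fresnel-zone
  widths (~35 µm at 60 keV, 12 m).
* **Sub-pixel registration.** Binned to 50-µm pixels, a ~40-µm fringe
  pair spans 1–3 pixels depending on where pixel boundaries fall.
  `edge_width_detector_limited()` therefore reports the median over a
  uniform sweep of sub-pixel offsets — the canonical detector-limited
  width, 2 pixels = 100 µm at 60 keV and z = 12 m.
* `wall_thickness_estimate()` identifies the inner (air/wall) and outer
  (wall/parenchyma) fringes on each side of the lumen as adjacent
  overshoot/undershoot extremum pairs, using an orientation rule — a
  primary interface fringe carries its trough on the wall side of its own
  center, while diffraction-ringing pairs alternate — to reject ringing.
  The wall border marker is the undershoot trough with parabolic
  sub-sample refinement. The midpoint of the extremum pair (available as
  `method = "midpoint"`) systematically overestimates the wall by roughly
  one Fresnel-zone width, because the tangent-ray caustic of the curved
  interface displaces the overshoot deep into the low-phase side; the
  trough tracks the geometric border to a few micrometres at fine pitch.
  When the two troughs merge at coarse pixels (a 0.1-mm wall on 50-µm
  pixels), the estimator falls back to the pair-midpoint distance.
* **Recovery curve.** Errors are ≈5 µm at ≤10-µm pitch and grow to a few
  tens of µm at 50-µm pixels — detector-resolution-limited. Because the
  error of a binned estimate is only defined up to the half-pixel
  quantization of the coarser measurement, the monotonicity of the
  recovery curve is asserted with exactly that equivalence scale.

## Problem sizes

The reference runs use an 8-mm transverse window at 2.5-µm pitch
(N = 3200, padded to 8192 for the FFT), chosen so that the full airway
sweep, oracle comparisons and recovery curves execute in seconds on a
single core while satisfying the sampling bound at every distance in the
2–12 m sweep. 2D nodule ROIs default to 12 mm at 5-µm pitch.

## Known limitations

* Projection approximation only: thick objects are a single phase screen;
  multi-slice propagation is out of scope.
* Parallel-beam propagation core; cone beams are handled by the design
  module's effective-distance rescaling, not a divergent propagator.
* Polychromatic propagation at $z > 0$ (per-bin coherent, incoherent sum)
  is implemented but marked experimental behind a flag; the reference
  chain propagates monochromatically.
* No Compton-scatter background, charge sharing, spectral response or
  pile-up; no vendor post-processing (an optional generic display
  operator is *not* a reproduction of any vendor algorithm).
* Homogeneous parenchyma: absolute visibility numbers will exceed what a
  textured lung background would yield.
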