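Package: pbisim
Title: Propagation-Based Phase-Contrast X-Ray Radiography Simulator
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Wave-optics simulation of propagation-based phase-contrast
    (PBI) X-ray radiography of soft-tissue phantoms. Builds analytic
    airway and nodule phantoms, projects them into per-material thickness
    maps, converts the maps to complex exit wavefronts (phase from the
    refractive-index decrement, amplitude from Beer-Lambert attenuation),
    performs single-distance Fresnel free-space propagation with a
    spectral transfer-function method, and models an idealized
    photon-counting detector (Gaussian blur, pixel binning, Poisson
    counting noise). Includes fringe metrics (edge-enhancement width,
    visibility, airway wall-thickness estimation) and the PBI
    system-design calculus (Fresnel-zone width, wavefront-sampling bound,
    transverse coherence, magnification and effective propagation
    distance).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
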