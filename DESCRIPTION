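Package: BeamTrack
Title: Two-Directional Beam-Tracking X-ray Phase-Contrast Tomography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for two-directional beam-tracking (2DBT) X-ray
    phase-contrast imaging. A high-Z amplitude modulator structures the
    beam into a grid of beamlets whose intensity and subpixel position
    changes encode, respectively, sample attenuation and refraction.
    The package provides a geometrical-optics simulator of beamlet
    frames from known phantoms, per-beamlet retrieval of transmission
    and two-directional refraction angles by upsampled cross-correlation,
    sub-pitch stitching of raster scans, Fourier-space integration of
    the two phase gradients into phase maps, parallel-beam filtered back
    projection of attenuation and refractive-index-decrement volumes,
    and characterization metrics: angular sensitivity, modulation
    visibility, power-law trend fits, and Fourier ring correlation
    resolution with a 3-sigma threshold.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'BeamTrack-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'core.R'
    'simulator.R'
    'tracking.R'
    'phase.R'
    'tomo.R'
    'metrics.R'
    'io.R'
    'pipeline.R'
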