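Package: ntcsim
Title: Desk-Scale Digital Twin of a Non-Telecentric Two-Photon Scan Engine
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Paraxial ray-matrix and Gaussian-beam model of a two-photon
    microscope excitation path in its diffraction-limited (DL) and
    non-telecentric (nTC1, nTC2) configurations. Predicts field of view,
    effective excitation numerical aperture, two-photon point-spread-function
    size, focal shift, field curvature and back-aperture vignetting;
    synthesizes 3D scan trajectories (raster, random-access, staircase,
    tilted, halfpipe, multiplane) with line-synchronized galvo, electrically
    tunable lens (ETL) and Pockels command waveforms; renders simulated
    acquisitions from synthetic bead and soma phantoms with calcium-like
    activity; and implements the matching image and trace analyses (Gaussian
    FWHM fits, bead-stack PSF estimation, radial brightness profiles,
    neighbour-correlation activity maps, z-scored traces and event-triggered
    averages).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    tiff,
    optparse
Config/testthat/edition: 3
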