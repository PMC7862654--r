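Package: iontomo
Title: Ion Beam Tomography Reconstruction and Spatial Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation, reconstruction and quantification of multi-depth
    secondary-ion mass spectrometry (NanoSIMS/MIBI) image stacks. Implements a
    physical forward model (object convolved with a beam point-spread function,
    scaled by ion extraction efficiency and contaminated by multiplicative gamma
    noise), sliding-window depth binning, hybrid Lucy-Richardson deconvolution
    with a beam-current-dependent blind PSF, secondary ion-beam localization
    microscopy (SILM) reconstruction, fiducial-bead drift registration,
    edge-spread-function resolution estimation, image-similarity metrics, and a
    spatial-statistics layer (fuzzy C-means chromatin-state segmentation,
    multichannel voxel K-means, block peak counting, pairwise peak distances,
    hierarchical clustering, channel correlation matrices and Delaunay
    neighborhood analysis).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tiff,
    jsonlite,
    yaml,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    e1071,
    withr
Config/testthat/edition: 3
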