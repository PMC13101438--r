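Package: axonmorph
Title: Axon and Myelin Morphometry for CARS Microscopy of White Matter
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-segmentation morphometry of myelinated nerve fibers in
    coherent anti-Stokes Raman scattering (CARS) microscopy images of white
    matter. Separates 3-class semantic masks (background/myelin/axon) into
    per-fiber instances, computes area-equivalent axon and fiber diameters,
    myelin thickness, g-ratio, eccentricity and fiber density, applies
    multicriteria quality-control screening, and aggregates populations into
    diameter-binned summaries with correlation structure. Includes a seeded
    synthetic image generator that emulates CARS cross-sections of myelinated
    fibers with exact ground truth, segmentation evaluation metrics (Dice,
    IoU), and spectral-focusing CARS pulse calculations (Raman-shift
    targeting, transform-limited and chirped pulse durations, group delay
    dispersion, spectral FWHM, delay-scan cross-correlation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
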