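Package: vigorspec
Title: Hyperspectral Prediction of Seed Vigor Traits
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Chemometric pipeline for predicting seed germination traits
    (root length, seedling length) from visible/near-infrared hyperspectral
    images of individual seeds. Covers white/dark reference reflectance
    calibration of raw hypercubes, elliptical region-of-interest spectrum
    extraction, spectral windowing, wavelength selection by correlation
    ranking (HCC), the successive projections algorithm (SPA) and a genetic
    algorithm (GA), Kennard-Stone train/test splitting, and principal
    component regression (PCR), Gaussian-kernel principal component
    regression (KPCR) and partial least squares (PLS) regression, with a
    model-comparison grid reporting correlation coefficient and RMSE per
    (selection x model x trait) cell. Includes a synthetic-study generator
    with known ground truth for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    tiff,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    withr,
    yaml,
    optparse
biocViews: Regression, FeatureExtraction, Preprocessing
Config/testthat/edition: 3
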