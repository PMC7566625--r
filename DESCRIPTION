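Package: vistain
Title: Virtual Immunofluorescence Staining of H&E Histology with
    Feature-Guided Sample Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for learning and evaluating virtual immunofluorescence
    (IF) staining from hematoxylin-and-eosin (H&E) histology images.
    Provides seeded synthetic phantom cohorts of spatially registered
    H&E/IF image pairs; a preprocessing pipeline (downscaling, nuclei-mask
    affine registration, disk median filtering, intensity normalization,
    background-filtered tiling); variational-autoencoder tile features;
    an information-theoretic, weighted Kullback-Leibler greedy algorithm
    for representative sample selection; a conditional adversarial
    image-to-image translator with an adaptive stain-prevalence L1 weight
    (plus an L1-only ablation mode, ensembling and tile stitching);
    windowed SSIM and Pearson evaluation with a paired nonparametric
    model-comparison battery; and end-to-end experiment orchestration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    Rcpp,
    EBImage,
    SummarizedExperiment,
    S4Vectors,
    jsonlite,
    yaml,
    tiff
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    png
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
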