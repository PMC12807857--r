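Package: mitoinherit
Title: 3D Mitochondrial Morphometry, Age Stratification and Asymmetric
    Inheritance Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies mitochondrial inheritance and architecture in
    dividing cells from multi-channel 3D fluorescence stacks. Provides
    per-organelle segmentation (isotropic resampling, channel fusion,
    outline enhancement, multi-Otsu thresholding, morphological cleanup
    and a size filter), 3D morphometry (marching-cubes surface area,
    sphericity, complexity index, roundness, solidity), age-label
    intensity stratification of organelles into lo/mid/hi strata, the
    daughter-cell asymmetric-inheritance score (P1-P2)/(P1+P2) with its
    1.5x-ratio classification rule, histone proteomic-ruler copy-number
    estimation with a differential-inheritance filter, and nonparametric
    group statistics (Welch t, Kruskal-Wallis/Dunn with Bonferroni
    correction). A synthetic-data module generates ground-truthed stacks,
    daughter pairs and protein tables so the whole pipeline is testable
    without imaging or mass-spectrometry downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
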