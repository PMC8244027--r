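Package: rsfavasc
Title: Vascular Contributions to Age Differences in Resting-State BOLD
    Signal Variability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to estimate resting-state fluctuation amplitude (RSFA)
    maps from BOLD fMRI time series via a nuisance general linear model
    with simultaneous discrete-cosine band-pass filtering, derive latent
    cardiovascular-health factors from peripheral measures, decompose
    subject-by-voxel modality maps with group spatial independent component
    analysis (MDL order selection), and test whether age effects on RSFA
    are explained by cardiovascular and cerebrovascular predictors using
    two-stage robust residual regression, FDR-corrected residual-age
    correlation maps, and a distribution-shape permutation test based on
    Kolmogorov-Smirnov similarity profiles. Includes a synthetic multimodal
    cohort generator with planted vascular mediation structure for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    RNifti,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
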