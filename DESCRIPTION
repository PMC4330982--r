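Package: fociscreen
Title: Gamma-H2AX Foci Quantification and Radiosensitivity Outlier Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies gamma-H2AX foci per lymphocyte nucleus from two-channel
    fluorescence z-stacks (maximum-intensity projection, DAPI nucleus
    segmentation with objective apoptotic exclusion, Laplacian-of-Gaussian spot
    counting), determines how many cells must be scored for a stable
    per-individual foci rate via cumulative-mean agreement at fixed
    checkpoints, fits Gaussian cohort distributions with normality testing
    (Kolmogorov-Smirnov and Monte-Carlo Lilliefors), and classifies
    individuals as radiosensitivity outliers by standard-deviation exceedance
    with a three-class taxonomy. Ships a synthetic cohort and microscope
    simulator with planted ground truth so the full pipeline is testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    graphics,
    grDevices,
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    nortest,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
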