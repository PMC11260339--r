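Package: vibrostage
Title: Vibrational Spectroscopy Metrics and Chemometrics for Staging Cell
    Differentiation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for staging stem-cell differentiation (adipogenesis of
    adipose-derived mesenchymal stem cells) from FTIR and Raman spectra.
    Provides readers and writers for spectrum tables and focal-plane-array
    hyperspectral cubes, a synthetic spectra generator that emulates
    stage-dependent band profiles, the full IR and Raman preprocessing chains
    (cosmic-ray removal, polynomial and rubber-band baselines, Savitzky-Golay
    smoothing and second derivatives, CO2-band flattening, PCA denoising,
    signal-to-noise ROI selection, vector normalization, outlier rejection),
    band-integration metrics for lipids, proteins and DNA with ANOVA/Tukey
    group statistics and integral-intensity chemical maps, and a chemometric
    layer: Ward/Euclidean hierarchical clustering, mean-centered PCA, and
    NIPALS partial-least-squares regression with leave-one-out
    cross-validation and held-out two-class classification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    pracma,
    signal,
    stats,
    utils,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
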