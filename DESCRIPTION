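Package: vibrafuse
Title: Dual-Modality Vibrational Spectroscopy Fusion for Lipid
    Composition Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Chemometric workflow for predicting the lecithin to
    sphingomyelin (L/S) ratio of lipid vesicles from paired ATR-FTIR and
    Raman spectra. Provides a seeded synthetic generator for paired
    two-lipid mixture spectra with realistic artifact structure (negative
    water bands, silicon substrate band, fluorescence baseline, cosmic
    spikes, scatter variation), spectral preprocessing (despiking,
    baseline offset, region-anchored standard normal variate), partial
    least squares regression with cross-validated F-statistic latent
    variable selection, distribution-free jackknife+-after-bootstrap
    prediction intervals, low-level (concatenation) and high-level (mean
    and inverse-variance weighted) data fusion, and prediction-interval
    figures of merit (PICP, ACE, PINAW) reported in a five-model
    comparison table.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr,
    zoo
Suggests:
    mixOmics,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
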