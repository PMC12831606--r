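Package: optodesens
Title: Simulation and Analysis of Opsin Desensitization in All-Optical Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying channelrhodopsin response desensitization in
    two-photon all-optical interrogation experiments. Provides a mean-field
    two-photocycle kinetic model of opsin ground-state depletion driven by
    holographic photostimulation trains and calcium-imaging laser exposure, a
    synthetic-session generator emitting labelled ROI fluorescence traces with
    GCaMP6s-like transients, the full trial quantification chain (stimulus-
    triggered delta-F/F, responsiveness screening, population response AUC,
    normalized decay curves, two-term exponential and linear fits), beamlet-
    geometry target assignment with correlation-based network classification,
    and cohort-level nonparametric statistics across imaging-dose and
    inter-stimulus-interval conditions.
License: MIT + file LICENSE
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
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    tiff
Config/testthat/edition: 3
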