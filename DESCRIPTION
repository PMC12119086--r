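Package: hemoccl
Title: Quantifying Hemodynamic Occlusion in Two-Photon Fluorescence Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify the contribution of hemodynamic occlusion --
    the time-varying shadowing of fluorophores by dilating and constricting
    blood vessels -- to two-photon fluorescence imaging signals. Provides a
    forward simulator of imaging scenes with vessel-coupled occlusion, rigid
    frame registration and percentile-baseline dF/F0 extraction, locomotion
    and stimulus onset detection, event-triggered response analysis with
    per-neuron responsiveness tests and random-trigger chance bands,
    hierarchical (site-then-neuron) bootstrap statistics, blood-vessel
    cross-section estimation by ellipse fitting, variance-explained
    attribution, and behavioral-state-dependent pairwise correlations.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    readr,
    zoo,
    tiff,
    jsonlite,
    yaml,
    EBImage,
    stats,
    utils,
    generics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
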