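Package: nmtf
Title: Diaphragm Neuromuscular Transmission Failure and NMJ Morphometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulation and analysis of diaphragm neuromuscular transmission
    failure (NMTF) assessed with the superimposed-stimulation technique, and
    of neuromuscular junction (NMJ) pre/post-synaptic morphometry from
    two-channel confocal z-stacks. Provides a parametric generator of
    isometric force recordings under repetitive 40 Hz phrenic nerve
    stimulation with periodic direct muscle stimulation, train detection and
    the NMTF, intratrain-fatigue and specific-force statistics, a synthetic
    NMJ stack renderer with ground-truth masks, projection/threshold/overlap
    morphometry, and the accompanying statistical reporting layer
    (Shapiro-Wilk, two-SD outlier exclusion, one- and two-way ANOVA with
    Tukey or Bonferroni post-tests, and power-based sample sizing).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
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
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
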