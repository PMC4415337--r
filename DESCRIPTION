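Package: specsim
Title: Theoretical Tandem Mass Spectrum Prediction from Adjacent y-Ion
    Intensity Ratios
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts theoretical CID/HCD tandem mass spectra of doubly
    charged tryptic peptides from a closed-form mobile-proton model of the
    intensity ratio of adjacent y ions. Provides least-squares training of
    the model parameters from annotated spectra, spectrum similarity scoring
    (Pearson correlation, square-root spectral similarity, shared-peak
    counts), re-ranking of SEQUEST and X!Tandem peptide-spectrum matches
    with decoy-count false discovery rate analysis, a seeded synthetic-data
    generator for end-to-end validation, and readers and writers for Mascot
    Generic Format peak lists and tab-separated PSM tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
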