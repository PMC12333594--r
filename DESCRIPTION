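Package: hemiphase
Title: Interhemispheric EEG Phase Asymmetry and Spectral Lateralization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Analysis pipeline for condition-dependent interhemispheric
    asymmetries in multi-channel EEG epochs: event-related potential (ERP)
    condition contrasts over 100-ms windows, left-minus-right difference
    waveforms for homologous electrode pairs with component-window statistics,
    Hilbert-transform instantaneous phase and the conditioning interhemispheric
    phase-shift statistic referenced against a balanced-resampling null
    distribution, regression-based interhemispheric frequency-divergence
    estimation, and power-spectral-density spectral-centroid lateralization
    tests. Includes a seeded synthetic EEG generator that emulates a
    two-condition face-observation paradigm with known injected effects, so
    every stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    emmeans,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
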