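Package: srqafib
Title: Symbolic Recurrence Quantification Analysis of RR Intervals for
    Atrial Fibrillation Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects atrial fibrillation in beat-annotated RR-interval time
    series using symbolic recurrence quantification analysis (SRQA).
    Windows of consecutive RR intervals are mapped to ordinal-pattern
    symbols, symbolic recurrence matrices are quantified (recurrence rates
    per symbol, determinism, trapping time, line entropies), and the
    resulting covariates, together with simple RR dispersion statistics,
    feed a logistic classifier with ROC-based threshold selection and
    stratified K-fold cross-validation. Includes a synthetic generator of
    sinus-like and fibrillation-like RR records, readers and writers for a
    plain-text RR record format, an adapter for text-exported PhysioNet
    annotations, and a command-line interface.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
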