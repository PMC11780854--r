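Package: probeval
Title: Evaluation of Transcriptome-Scale RNA Chemical Probing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating RNA chemical probing experiments (DMS and
    SHAPE, read out by reverse-transcription stops or mutational profiling)
    against reference secondary and tertiary structure. Computes per-base
    stop and mutation rates from event-count tables, applies coverage and
    base-identity filters, optionally subtracts a probe-free background
    channel, and scores concordance with dot-bracket reference structures
    via ROC/AUC and top-x% unpaired fractions. Also provides marginal
    pairing probabilities from base-pair probability matrices with an
    exhaustive-enumeration toy ensemble as internal oracle, Shrake-Rupley
    solvent-accessible surface area on RNA coordinates with reactivity
    correlation, and a generative simulator of probing experiments with a
    known ground-truth structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    utils
LinkingTo: Rcpp
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
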