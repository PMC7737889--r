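Package: olfcoh
Title: Olfactory EEG Coherence and Smell-Test Biomarkers for Mild Alzheimer's Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for olfactory biomarkers of mild Alzheimer's
    disease combining two measurement channels: imaginary-part-of-coherence
    (ImCoh) features computed from four-channel EEG recorded during an
    olfactory oddball task, and item-level scoring of a 24-item forced-choice
    smell identification test. Provides Welch cross-spectral density
    estimation, band-averaged ImCoh features per electrode pair, zero-phase
    band-limiting, decimation, ICA-based blink removal, epoch extraction and
    peak-to-average artifact rejection, Welch t-tests with Benjamini-Hochberg
    false discovery rate control (optionally using an effective number of
    tests for correlated features), age-residual adjustment against the
    healthy-group regression line, and stratified cross-validated linear
    support-vector-machine classification of single- and multi-modal feature
    sets. A seeded synthetic-cohort generator with analytic coherence oracles
    makes every stage testable without access to clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    e1071,
    pROC,
    withr,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
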