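Package: nosejudge
Title: Electronic-Nose Breath Classification with Tucker3 Compression and
    a Gated Neural-Network Judge Ensemble
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for temperature-modulated metal-oxide
    electronic-nose breath measurements. Each breath sample is a 3-way
    conductivity array (64 temperature steps x 36 measurement cycles x 3
    sensors) that is preprocessed, compressed with a Tucker3 decomposition
    (HOSVD initialisation, higher-order orthogonal iteration refinement),
    and classified by a gated ensemble of small feed-forward neural
    networks (a "judge" model: one gating network routing each sample to
    one of two three-member committees whose outputs are averaged). Model
    selection is an exhaustive search over trained candidate networks
    inside the inner loop of a double (nested) cross-validation; pooled
    out-of-fold predictive values in [-1, 1] are thresholded at zero and
    summarised by sensitivity, specificity, accuracy, the Matthews
    correlation coefficient, ROC curves and bootstrap confidence
    intervals. A synthetic cohort generator emulates the measurement
    structure (class-dependent low-multilinear-rank response signatures,
    per-device multipliers, multiplicative log-normal sensor noise) so the
    whole pipeline is testable without patient data; baseline-characteristic
    tests (t, Fisher exact by enumeration, Pearson chi-square) reproduce
    the usual cohort-table workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
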