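Package: sevscore
Title: Continuous Disease-Severity Scores from Ordinal Image Labels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Trains convolutional image models on discrete ordinal severity
    labels and converts their outputs into calibrated continuous severity
    scores. Implements four model families (multi-class, CORAL ordinal
    classification, regression, twin networks), Monte Carlo dropout
    inference with spatial dropout, affine score rescaling to a 1-9 expert
    scale, and a rank-agreement evaluation protocol (Spearman correlation,
    normalized-rank MSE, clinically relevant AUROC, fine-rating MSE,
    temporal-change MSE) with bootstrap confidence intervals and pairwise
    model comparison. A synthetic severity-image generator with a continuous
    latent severity, threshold discretization, simulated multi-rater fine
    ratings, expert rank lists, and longitudinal image pairs makes the whole
    pipeline testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    png,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
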