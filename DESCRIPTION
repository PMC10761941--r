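Package: musedetect
Title: Emergence of Music-Selective Units in Sound-Event-Detection Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained pipeline for studying how music-selective units
    can emerge in a convolutional multi-label sound-event tagger that is never
    trained on music. Provides a seeded synthetic-soundscape generator
    (harmonic music, speech-like, impulsive and textural categories), a
    log-Mel spectrogram frontend with amplitude controls, a compact
    convolutional tagger trained with binary cross-entropy, AdamW and a
    one-cycle learning-rate schedule, spectro-temporal Gabor filter-bank and
    PCA linear baselines, per-unit selectivity indices (Welch-style t
    statistics) with top-fraction unit groups, sound-quilt stimulus
    generation that destroys long-timescale structure while preserving
    short-timescale structure, linear probes and t-SNE embeddings of feature
    spaces, unit-ablation experiments, and the nonparametric statistics
    (average precision, Wilcoxon tests, common-language effect size) used to
    evaluate them.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    cluster,
    Rtsne
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    knitr,
    ggplot2
Config/testthat/edition: 3
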