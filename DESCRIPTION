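Package: semprime
Title: Distributional Semantic Spaces and Similarity-Stratified Lexical
    Priming Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying whether distributional semantic similarity
    predicts lexical priming. Builds LSA-type (word-by-document) and HAL-type
    (windowed word-by-word) semantic spaces from tokenized corpora via
    positive pointwise mutual information weighting and truncated singular
    value decomposition; generates similarity-stratified prime-target item
    sets under lexical matching constraints with Latin-square block plans;
    simulates lexical-decision reaction times from a crossed random-effects
    generative model over a synthetic Zipfian corpus; and fits the
    corresponding linear mixed-effects analyses with likelihood-ratio tests,
    Wald confidence intervals and AIC-based model comparison.
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
    lme4,
    Matrix,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
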