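Package: colonynet
Title: Multilayer Analysis of Social Network Position in Ant Colonies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dissecting the correlation structure among the social
    environment, physical environment, age, behavior, brain gene expression,
    and gut microbiota composition of individually tracked ant workers.
    Includes a synthetic colony simulator, pairwise interaction inference
    from frame-level tag detections, soft two-community decomposition of
    weighted interaction networks yielding a continuous social maturity
    score, multiplex network construction with interlayer R-squared
    correlation networks, a negative-binomial Wald differential expression
    engine with Benjamini-Hochberg correction and controlled two-covariate
    designs, and resampled support-vector-regression prediction of
    individual traits from brain expression profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    MASS,
    e1071,
    lme4,
    jsonlite,
    readr
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2
Config/testthat/edition: 3
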