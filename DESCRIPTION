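Package: sevlip
Title: Differential Abundance and Signature Discovery for Extracellular-Vesicle Lipidomics Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for targeted lipidomics panels measured on
    serum small extracellular vesicles (sEV) in multi-group screening studies.
    Covers the two-type missing-value policy (below limit-of-quantitation
    versus internal-standard failure), truncated-normal and k-nearest-neighbour
    imputation, empirical-Bayes batch correction of 96-well plate effects,
    permille normalization, Kruskal-Wallis and Conover-Iman differential
    abundance with effect sizes, presence/absence chi-squared analysis, and a
    nested cross-validated biomarker-signature procedure (forward BIC feature
    selection for multinomial logistic regression inside multiple random
    cross-validation, with feature ranking, elbow extraction and
    Youden-thresholded binary models). Includes a synthetic-panel generator
    emulating the statistical structure of such studies so that every stage is
    testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    cluster,
    dplyr,
    generics,
    ggplot2,
    rlang,
    readr,
    stats,
    sva,
    tibble,
    tidyr,
    utils,
    vegan,
    withr
Suggests:
    nnet,
    pROC,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
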