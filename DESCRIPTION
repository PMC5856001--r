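Package: dsbpredict
Title: Kilobase-Resolution Prediction of DNA Double-Strand Breaks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts endogenous DNA double-strand break (DSB) sites from
    epigenomic occupancy, DNA motif occurrences and DNA shape. Builds
    GC/repeat/size-matched non-DSB control sets, featurizes sites with
    peak-overlap fractions, JASPAR position-weight-matrix hit counts and
    pentamer-lookup DNA-shape summaries, trains random-forest and
    L1-penalized logistic classifiers, evaluates them with ROC and
    precision-recall curves including bootstrap confidence intervals, and
    scores whole genomes in fixed-width bins. Ships a synthetic-data
    generator (toy genomes, planted DSB sites, conditionally associated
    peak tracks, planted motifs, stand-in shape table) so the entire
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    glmnet,
    withr,
    jsonlite,
    stats,
    utils,
    tools,
    IRanges,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
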