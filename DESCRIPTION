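Package: salivr
Title: Predicting Blood-Derived Salivary Proteins and Candidate Saliva Biomarkers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Sequence-based prediction of human proteins that can move from
    blood circulation into saliva, and integration of those predictions with
    differential expression evidence to prioritise candidate saliva biomarkers.
    Computes per-protein sequence descriptors (amino-acid and dipeptide
    composition, Moreau-Broto/Moran/Geary autocorrelation over physicochemical
    scales, composition-transition-distribution descriptors, disorder and
    secondary-structure summaries), performs two-stage feature selection
    (permutation test with Storey q-values, then SVM recursive feature
    elimination), trains and cross-validates a linear support-vector
    classifier, ranks background proteins by manifold ranking on a Gaussian
    similarity graph, and scores candidate overlaps with hypergeometric
    enrichment. Includes a synthetic-data generator that emulates the
    statistical structure of the training corpora and of paired case/control
    expression cohorts, so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    e1071,
    ggplot2,
    generics,
    purrr,
    readr,
    rlang,
    seqinr,
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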