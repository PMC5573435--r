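Package: kmervote
Title: Two-Stage Taxonomic Classification of Metagenomic Fragments by
    k-mer SVM Ensembles with an Alignment Fallback
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Classifies short metagenomic sequence fragments to species
    using an ensemble of L2-loss linear support vector machines, one per
    k-mer size (default k = 6..10), trained on sparse k-mer count
    profiles of a labelled reference genome collection.  Majority voting
    across the ensemble partitions query fragments into a confident set
    (consistent member predictions) and a diffident set; diffident
    fragments are reclassified by the best local-alignment hit against
    the reference set, or tagged unknown when no hit satisfies the
    e-value (and optionally identity) policy.  Includes a synthetic
    genome-collection simulator (species-distinct Markov composition,
    non-overlapping shredding, substitution errors), staged evaluation
    reports (accuracy, sensitivity, specificity, true positives) and a
    command-line pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    methods,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
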