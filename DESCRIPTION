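Package: ajnet
Title: Co-Expression Network Stratification of Tumor Proteomes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds sparsified Pearson co-expression networks over quantified
    proteomes, extracts protein modules with a from-scratch Markov Cluster
    Algorithm, annotates them by hypergeometric overrepresentation analysis,
    and stratifies patients into high/low expressors of a selected module
    (such as the adherens-junction complex) by K-means. Downstream analyses
    cover empirical-Bayes moderated-t differential expression with a dual
    significance rule, matrisome (extracellular matrix) partitioning, exact
    Fisher and Wilcoxon association tests, and Euclidean proteome-distance
    comparisons between histological subgroups. A synthetic-cohort generator
    with planted modules and ground-truth labels makes the full pipeline
    testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    limma,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
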