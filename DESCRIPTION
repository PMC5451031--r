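Package: essprofile
Title: Feature Profiling of Essential Versus Viable Genes
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A reproducible pipeline for contrasting essential (lethal-knockout)
    and viable mouse genes across genomic, protein-sequence, expression,
    evolutionary-age and protein-protein interaction network features.
    Implements EST-to-TPM normalisation over thirteen developmental stages,
    duplication-aware gene-age assignment (MRD/DCA/SCA) from annotated gene
    trees, sequence-redundancy culling at identity thresholds, the nine
    per-node PPI topology scores (degree, average shortest path, betweenness,
    clustering coefficient, closeness, BottleNeck, EPC, MNC, DMNC), and
    two-group statistical comparison (Kolmogorov-Smirnov normality gate,
    Welch t / Mann-Whitney U, Pearson chi-squared, Fisher exact) under
    Bonferroni family-wise control. A seeded synthetic-cohort generator
    emulates the two-group study design so the full pipeline is testable
    without database downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    igraph,
    ape,
    Biostrings,
    nortest,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
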