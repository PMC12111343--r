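Package: miRPair
Title: Integrative miRNA-mRNA Differential Expression and Anti-Correlated
    Target Pairing
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An integrative analysis pipeline for paired miRNA and mRNA
    expression profiles from small multi-group designs, modelled on rat
    adrenal profiling under gonadectomy and sex-hormone replacement.
    Provides empirical-Bayes moderated t-tests with a compound fold-change
    and FDR cut-off, multi-database miRNA target aggregation with
    inverse-fold-change pair calling, hypergeometric gene-set enrichment,
    K-means co-expression clustering with SSE elbow selection and
    correlation-filtered core members, concordance checks against external
    differential-expression tables, and a synthetic-data generator with
    planted ground truth so that every stage is testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    limma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
biocViews: GeneExpression, DifferentialExpression, Microarray, Clustering,
    GeneSetEnrichment
RoxygenNote: 7.3.3
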