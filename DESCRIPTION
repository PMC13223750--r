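Package: kpnad
Title: Kynurenine-Pathway Bottleneck Analysis for Longitudinal IBD Multi-Omics
Version: 0.1.0
Authors@R:
    person("Kiel", "Metabolomics Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects metabolic bottlenecks in de novo NAD+ synthesis from
    tryptophan in longitudinal inflammatory bowel disease cohorts. Provides
    targeted-metabolomics preprocessing (80 percent missingness rule,
    half-minimum imputation, log10 transform with autoscaling, kynurenine
    pathway ratio panel), gene-protein-reaction rule parsing and
    expression-conditioned reaction activity scores over the
    tryptophan-degradation subnetwork, linear mixed-model association of
    reactions, metabolites and ratios with disease activity (including
    logarithmic-decline imputation of missing activity scores,
    Benjamini-Hochberg correction, remitter/non-remitter timepoint contrasts
    and Spearman correlations with FDR), permutation GSEA and rank-based
    single-sample gene-set scoring, and a seeded synthetic-cohort generator
    with planted IDO1/QPRT effects so the whole chain is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
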