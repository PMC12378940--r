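Package: momdep
Title: Multi-Omics Metabolomics Pipeline for Depression Pathway Tiering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested, reusable pipeline for multi-omics metabolomics studies
    of late-life depression. Implements cohort screening with GDS-30 scoring
    and 1:1 age/sex frequency matching; internal-standard normalization;
    OPLS-DA with VIP scoring and permutation validation; weighted metabolite
    co-expression network analysis (soft thresholding by scale-free fit,
    topological overlap, module eigengenes, module-membership and
    trait-significance hub screening); two-sample Mendelian randomization on
    GWAS summary statistics (instrument selection, LD clumping,
    harmonization, Steiger filtering, IVW, MR-Egger, weighted median, simple
    mode, and heterogeneity sensitivity analyses); hypergeometric pathway
    enrichment with relative-betweenness impact scoring; and a rule-based
    Class I/II/III(/III*) pathway-tier classifier that merges the three
    evidence streams into a high-confidence metabolite pool. A
    synthetic-data generator with known ground truth (planted differential
    features, correlated metabolite blocks, GWAS pairs with a planted causal
    effect, toy pathway graphs) makes every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
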