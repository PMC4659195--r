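Package: exorep
Title: Technical-Replicate Exome Coverage Concordance and Trio De Novo
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies the stochastic variability between technical-replicate
    exome capture libraries from per-base depth-of-coverage tables.
    Implements the intersection-union analysis of replicate coverage masks
    (Venn region counts, variable-base fractions, two-proportion testing),
    aggregation of replicates and extraction of the targeted segments
    recovered by deeper data, depth-binned inter-replicate genotype
    discordance with a binomial Bayesian genotype caller, and trio-based
    de novo mutation detection by Mendelian-inheritance violation.  A
    pedigree-aware synthetic data generator reproduces the statistical
    structure the analysis assumes (per-target capture efficiency,
    replicate library-size variation, overdispersed per-base depth,
    Mendelian transmission with injected de novo mutations) so the whole
    pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
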