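Package: pleiomap
Title: Multi-Trait GWAS Fine-Mapping with Linear Mixed Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Sequence-level association mapping of correlated quantitative
    traits in livestock-style cohorts. Implements mixed-model single- and
    multi-trait genome scans on allele dosages with a VanRaden genomic
    relationship matrix, permutation-calibrated effective numbers of tests
    (Sidak) and of traits (Galwey), QTL-region grouping across traits,
    LD-based and iterative Bayesian stepwise-selection (IBSS) credible sets
    with multi-trait merging, pleiotropy assessment from local test-statistic
    correlations, iterative conditional mapping, coding-variant enrichment
    tests (exact binomial, Poisson-binomial and Monte Carlo), and a
    haplotype-mosaic cohort simulator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
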