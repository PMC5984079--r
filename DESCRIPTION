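Package: rvburden
Title: Rare-Variant Burden Testing with Kernel Score Tests, Exact Rate
    Tests and Resampling-Based Family-Wise Error Control
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Gene-set and gene-wide burden analysis of rare and singleton
    coding variants in case-control and quantitative-trait cohorts. Variants
    are classified into nested functional tiers (disruptive; strictly
    damaging; broadly damaging) from consequence annotations and damage
    predictor verdicts, and tested with a variance-component kernel score
    test (analytic p-values from a mixture of chi-squared distributions via
    characteristic-function inversion with a moment-matching fallback) and a
    collapsing burden regression reporting odds ratios or effect sizes.
    Accumulation rates of qualifying alleles are compared between groups with
    an exact conditional Poisson test, and family-wise error rates within and
    across traits are controlled by Westfall-Young min-p resampling. A
    synthetic-cohort generator with a rare-skewed site frequency spectrum and
    plantable effects supports end-to-end testing and power studies without
    access to protected genotype data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    VariantAnnotation,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
biocViews: GeneticVariability, SNP, VariantAnnotation, StatisticalMethod,
    Genetics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
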