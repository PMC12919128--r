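Package: c9wta
Title: Wild-Type C9orf72 Allele Haplotype Modifiers of ALS Progression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Founder-haplotype inference and genetic modifier analysis for the
    wild-type C9orf72 allele (WTA) in repeat-expansion (C9-ALS) cohorts.
    Estimates two- and three-SNP founder-haplotype frequencies from unphased
    genotypes by expectation-maximization, assigns HRE carriers to the four
    ordinal WTA expression subgroups, and associates subgroup with disease
    duration via trimmed log10-survival regression and within-genotype
    carrier versus non-carrier t-tests. Includes the anchored piecewise-linear
    ALSFRS-R time-to-threshold statistic with a threshold robustness scan,
    single-basepair Tn5 cut-site footprint profiling with a per-base
    negative-binomial genotype-dose test, rule-based screens for severe
    expression outliers, allele-balance imbalance and carrier-unique splice
    junctions, and a synthetic cohort generator that emulates the assumed
    statistical structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    MASS,
    vcfR,
    yaml,
    GenomicRanges,
    IRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
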