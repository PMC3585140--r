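Package: alleleClock
Title: Allelic Age and the Neighborhood-Based Clock Statistic for
    Detecting Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects selection from allelic age rather than allele
    frequency. Provides diffusion-theory calculators for the mean age and
    sojourn-time density of an allele conditional on its current
    population frequency under genic selection, forward-in-time
    Wright-Fisher simulators (single-locus trajectories and an
    individual-based multi-locus simulator with recombination) that record
    true allele ages, the Neighborhood-based Clock (NC) statistic computed
    on phased haplotype panels via the four-gamete test and fully linked
    rarer variants, and downstream category statistics: frequency spectra
    by functional class, deleterious-fraction estimation against a neutral
    synonymous baseline, rank-based comparisons with bootstrap confidence
    intervals, and sample-size weighted Z-score meta-analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    pracma,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
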