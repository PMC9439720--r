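Package: svpanel
Title: Ensemble Structural-Variant Integration and Trio Cohort Panel QC
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for building and evaluating population-scale variant
    resources from trio-structured whole-genome cohorts: ensemble
    structural-variant (SV) call-set integration with reciprocal-overlap
    clustering and a learned boost-score filter, haplotype-panel site
    filtering with Hardy-Weinberg exact tests and male-X ploidy handling,
    trio-based quality metrics (Mendelian error, de novo, inheritance and
    transmission rates, singleton profiles), phasing-accuracy statistics
    (switch error rate, SV flip rate, parental flip rate), imputation
    performance evaluation (dosage r-squared, info score, hard-call
    discordance), dual-genotyper SV truth-set construction, and
    precision/recall benchmarking within confidence regions. Includes a
    synthetic trio-cohort generator with controlled de novo, caller error,
    phasing error and imputation noise rates for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    vcfR,
    xgboost,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
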