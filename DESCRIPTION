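Package: proteoMR
Title: Two-Sample Mendelian Randomization of Protein Biomarkers on Disease Risk
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end two-sample Mendelian randomization (MR) pipeline for
    circulating protein biomarkers as exposures and case-control disease status
    as outcome. Covers per-cohort association scans (rank-based inverse normal
    transformation, linear and logistic GWAS, variant QC, variance explained),
    cis-pQTL instrument selection with dual-cohort greedy LD pruning, generalized
    least-squares causal estimation over LD-correlated instruments (GSMR-style)
    with HEIDI outlier removal, correlated-instrument IVW, MR-Egger and weighted
    median sensitivity estimators, and FDR-controlled protein-by-disease grid
    reporting. Ships a synthetic paired-cohort generator so the whole pipeline is
    testable without access-restricted biobank data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
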