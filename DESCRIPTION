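Package: pathgwas
Title: Pathway-Based Genome-Wide Association Analysis with Permutation
    Significance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Pathway-level analysis of genome-wide association scans for
    quantitative traits. Implements SNP-level quality control (call rate,
    Hardy-Weinberg equilibrium, minor allele frequency, gene-distance
    filters), covariate selection and trait adjustment, additive
    single-SNP Wald regression, best-SNP-per-gene statistics, and a
    weighted Kolmogorov-Smirnov running-sum gene-set enrichment score
    with permutation-based normalized enrichment scores, nominal p
    values, and FDR/FWER multiple-testing control. Includes a synthetic
    GWAS-cohort generator with an embedded causal pathway for power and
    calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    nortest,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    fgsea,
    optparse
Config/testthat/edition: 3
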