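Package: fstscan
Title: Genome-Wide Fst Selection-Signature Scans for Multi-Breed SNP Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Detects candidate loci under selection from multi-breed SNP-chip
    genotypes. Reads PLINK-style PED/MAP files, applies sequential marker
    quality control (unmapped markers, minor allele frequency, call rate),
    estimates per-SNP multi-population Fst with a gamete-level nested-ANOVA
    (Weir-Cockerham-type) estimator including the unequal-sample-size
    correction factor, flags outliers in the upper tail of the empirical
    genome-wide Fst distribution, supports merged-group pairwise contrasts,
    maps outlier SNPs to annotated gene intervals, and summarises population
    structure by principal component analysis.  A Balding-Nichols genotype
    simulator with planted selected loci and planted quality-control defects
    provides ground-truth datasets for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    IRanges,
    S4Vectors,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
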