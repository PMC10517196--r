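Package: pathprs
Title: Pathway-Specific Polygenic Risk Scores for Brain Structure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds pathway-specific and genome-wide polygenic risk scores
    from GWAS summary statistics and target-cohort genotypes, and tests their
    association with neuroimaging regions of interest. Implements genotype and
    phenotype quality control (minor allele frequency, call rate,
    Hardy-Weinberg equilibrium, sample completeness, ROI outlier removal),
    SNP-to-gene-set annotation, allele harmonization of summary statistics,
    greedy LD clumping with P-value thresholding, APOE-region stratified
    scoring (with, without, or only the APOE locus), and a covariate-adjusted
    score-by-ROI linear regression grid with Benjamini-Hochberg FDR
    correction and incremental R2 attribution. A seeded synthetic-cohort
    generator with LD-block genotypes, a simulated discovery GWAS and planted
    pathway effects makes every stage testable without restricted cohort
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    fgsea,
    optparse,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
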