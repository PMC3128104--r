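Package: powerrep
Title: Power-Based Replication Enrichment for GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tests whether associations from one genome-wide association
    study replicate in a second study as a function of the statistical
    power to detect them. Provides per-SNP power calculators for
    case-control (noncentral chi-square allelic test) and quantitative
    (noncentral F) designs, harmonization of two summary-statistic
    tables onto a common effect allele, annotation of SNPs by distance
    to the nearest exon, logistic-regression enrichment models with
    exon-proximity and direction-of-effect interactions, excess
    replication counts by power stratum, permutation controls, simple
    LD pruning, polygenic scoring, and forward genotype-phenotype
    simulators that generate fully synthetic two-study datasets with
    known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
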