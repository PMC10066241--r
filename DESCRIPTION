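Package: divprs
Title: Polygenic Scoring and Expression Aggregates for Ancestrally Diverse Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An offline-testable pipeline for polygenic score analyses in
    ancestrally diverse case/control cohorts: PLINK1 binary genotype input
    and output, sequential genotype quality control (missingness,
    heterozygosity, exact Hardy-Weinberg, duplicate and strand-ambiguous
    variant removal, imputation-quality filtering), KING-robust kinship
    estimation with relationship classification and relative pruning,
    principal-component ancestry assignment against a labelled reference
    panel, GWAS summary-statistic harmonization, LD clumping,
    pruning-and-thresholding polygenic scores across a grid of p-value
    thresholds, incremental Nagelkerke pseudo-R-squared phenotype
    prediction, and a differential-expression-weighted aggregate gene
    expression score correlated with polygenic scores. A synthetic-data
    module generates Balding-Nichols population structure,
    liability-threshold phenotypes, analytic training-GWAS summary
    statistics, Mendelian relative pairs, and negative-binomial expression
    counts so that every stage is testable without access-controlled data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    limma,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
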