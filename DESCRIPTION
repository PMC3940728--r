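Package: countgwas
Title: Developmental GWAS of Overdispersed Count Phenotypes with GREML
    Heritability and Permutation-Based Significance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for genome-wide association
    studies of bounded, overdispersed count phenotypes measured
    longitudinally (e.g. behavioural screening scores at several ages).
    Provides a synthetic-data generator with block linkage disequilibrium
    and negative-binomial count traits; PLINK bed/bim/fam and dosage-table
    input/output with standard genotype quality control (minor allele
    frequency, call rate, Hardy-Weinberg equilibrium, imputation quality);
    genetic relationship matrices and GREML variance-component estimation
    (univariate SNP heritability with likelihood-ratio tests, bivariate
    genetic and residual correlations) on rank-based inverse-normal
    transformed covariate-adjusted residuals; per-SNP quasi-Poisson
    association scans with genomic-control correction; greedy LD clumping
    to index variants; and a jointly-permuted multi-phenotype genome-wide
    null for empirical familywise significance and candidate-gene
    co-location testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
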