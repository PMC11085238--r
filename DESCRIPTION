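Package: soypred
Title: Genomic Prediction of Soybean Seed Oil and Protein Content Across
    Structured Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools and an analysis workflow for within- and across-population
    genomic prediction of soybean seed oil and protein content. Provides a
    synthetic-data generator for structured germplasm panels (hierarchical
    Balding-Nichols drift) and biparental recombinant inbred line populations
    developed by single seed descent; genotype quality control and dosage
    coding; phenotype summarisation (best linear unbiased estimates across
    environments, ANOVA variance components, broad-sense heritability);
    population-structure analyses (PCA, Euclidean genetic distance, UPGMA
    clustering, distance-ranked training-set construction); whole-genome
    regression engines (REML G-BLUP and RR-BLUP, and Gibbs samplers for
    Bayesian ridge regression, the Bayesian LASSO and BayesB); and the
    cross-validation and sweep designs used to study how training-population
    composition, size and marker density drive prediction ability.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    e1071,
    jsonlite,
    MASS,
    stats,
    utils,
    vcfR
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
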