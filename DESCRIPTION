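Package: canidmix
Title: Microsatellite Admixture Analysis and Hybrid-Zone Scenario Testing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing hybrid zones between two divergent canid
    populations from noninvasively collected multilocus microsatellite
    genotypes. Implements replicate-PCR consensus genotyping with
    dropout/false-allele error control, individual identification via
    genotype matching and probability-of-identity statistics, standard
    population-genetic summaries (Hardy-Weinberg exact tests,
    Weir-Cockerham F-statistics, heterozygosity, allelic richness, and a
    Wahlund-effect regression), a Gibbs-sampler admixture model with
    correlated or uncorrelated cluster allele frequencies (with run
    alignment, Evanno delta-K model choice and cluster anchoring),
    gamete-based simulation of parental and hybrid-class genotypes, and a
    scenario-testing framework that solves population compositions
    against observed mean ancestry and compares ancestry distributions by
    Kolmogorov-Smirnov statistics and logistic-steepness fits. A
    synthetic-data generator reproduces the statistical structure of a
    two-species hybrid zone sampled across ordered geographic zones so
    the whole pipeline can be exercised without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    Rcpp,
    minpack.lm,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
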