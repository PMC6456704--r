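Package: episcan
Title: Two-Step Exhaustive SNP-SNP Epistasis Analysis for Case-Control Cohorts
Version: 0.1.0
Authors@R:
    person("Epistasis", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for detecting statistical epistasis between
    pairs of biallelic SNPs in case-control cohorts. Implements marker quality
    control (Hardy-Weinberg exact test, minor allele frequency), a
    covariate-adjusted single-SNP logistic scan with an independence screen that
    defines an additive background, a fast Kirkwood-superposition (BOOST-style)
    approximate interaction screen over all marker pairs using bit-level
    genotype encoding, an exact covariate-adjusted 4-degree-of-freedom
    likelihood-ratio interaction test with conditional analysis on the additive
    background, replication calls, orthogonal additive/dominance/epistasis
    effect decomposition, and observed-scale variance partitioning. Includes a
    synthetic case-control cohort generator with linkage-disequilibrium blocks,
    population structure, batch effects, and planted additive and epistatic
    architecture, plus PLINK bed/bim/fam input and output.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
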