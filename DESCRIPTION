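Package: genopred
Title: Two-Step Genomic Prediction with Bayesian Whole-Genome Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for multiple-step genomic evaluation of quantitative traits
    in livestock populations structured in paternal half-sib families. Provides
    a synthetic population generator (gene dropping from LD-structured founder
    haplotypes with contemporary-group and age effects), iterative SNP and
    sample quality control (MAF, Hardy-Weinberg, call rate, duplicate
    positions, windowed LD pruning), a pedigree animal model fitted by Gibbs
    sampling to produce estimated breeding values, prediction error variances
    and fixed-effect-adjusted phenotypes, three Bayesian whole-genome
    regression models (Bayesian ridge regression, BayesC and the Bayesian
    Lasso) with record weighting, VanRaden genomic relationships with
    training-validation relationship summaries, and k-fold cross-validated
    accuracy, bias and mean squared error of direct genomic values.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
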