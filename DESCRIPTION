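Package: markqg
Title: Quantitative Genetics of White Leg Markings in Horses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for ordinal white-leg-marking scores in
    pedigreed horse populations. Provides pedigree ingestion and ordering,
    Meuwissen-Luo inbreeding coefficients, the numerator relationship matrix
    and its sparse inverse via Henderson's rules; a synthetic-data generator
    for correlated four-limb liability-threshold phenotypes with direct and
    maternal genetic effects; descriptive prevalence and symmetry tables;
    a Bayesian cumulative-logit risk model with a dam random intercept;
    Bayesian threshold animal models (dichotomous and four-class ordinal,
    univariate and multi-trait) fitted by Gibbs sampling with liability
    augmentation; and posterior summaries with highest-posterior-density
    intervals, heritabilities and genetic correlations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    data.table,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
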