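Package: pigdamage
Title: Genetic Analysis of Ear and Tail Damage Traits in Group-Housed Pigs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pedigree-based linear animal models for ear and tail damage
    scores in group-housed pigs. Provides pedigree handling (additive
    relationship matrix, its sparse inverse, inbreeding), REML estimation of
    variance components with four random effects (animal, litter, pen group,
    herd-year-season of scoring) in univariate and bivariate form, BLUP
    breeding values with prediction error variances, seven derived damage
    trait definitions, three validation procedures for estimated breeding
    values (model-derived accuracy, replicated k-fold cross-validation with
    adjusted phenotypes, and forward validation by the linear-regression
    method), realized selection intensities, and predicted direct and
    correlated responses to selection. Includes a simulator for pedigrees and
    bivariate ordinal damage phenotypes with the assumed variance structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
LinkingTo:
    Rcpp
Config/testthat/edition: 3
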