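Package: qherit
Title: Quantile-Specific Narrow-Sense Heritability from Family Regression Slopes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates narrow-sense heritability of a quantitative phenotype as a
    function of its population quantile, from two-generation family data.
    Phenotypes are age- and sex-adjusted per cohort and averaged over repeated
    exams; weighted offspring-parent, offspring-midparent, full-sib and spouse
    pairs are built from the pedigree; weighted linear quantile regression
    (an interior-point check-loss solver) is fitted over a grid of quantiles
    with a bootstrap estimate of the covariance of the slope process; slopes
    are converted to heritability by the Falconer formulas and constancy of the
    slope process is tested with orthogonal-polynomial trend contrasts. A
    Gaussian-copula pedigree simulator with controllable margins and familial
    correlations makes the whole pipeline testable without restricted cohort
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
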