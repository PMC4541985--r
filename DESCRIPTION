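Package: sigpref
Title: Quantitative Genetics of Signal-Preference Covariation from Full-Sib
    Playback Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating genetic (co)variation in male advertisement
    signals and female mate preferences from full-sibling, split-family rearing
    experiments with vibrational playback assays. Provides a synthetic-data
    generator with known genetic architecture, cubic smoothing-spline
    estimation of individual mate-preference functions and their peaks,
    expected-mean-squares ANOVA with synthesized (Satterthwaite) denominators
    for mixed models, a Gibbs-sampler animal model over full-sib
    pseudo-pedigrees (univariate heritabilities and the bivariate cross-sex
    genetic correlation with residual covariance fixed at zero), reaction-norm
    style dissection of the signal-preference relationship, and comparison of
    among-family variation against species differences.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    lme4,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
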