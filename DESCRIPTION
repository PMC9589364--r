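Package: mrscreen
Title: Two-Stage Mendelian Randomization Screening with Bayesian Model
    Averaging for Correlated Metabolic Exposures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization screens of many
    correlated quantitative exposures (such as NMR metabolite panels)
    against binary disease outcomes, followed by Bayesian model averaging
    multivariable MR (MR-BMA) to rank the dominant causal traits.
    Implements summary-statistic reading and allele harmonization,
    instrument selection by genome-wide significance, LD clumping and
    F-statistic filtering, inverse-variance weighted, MR-Egger and
    weighted-median estimators with Cochran's Q, I-squared and H
    heterogeneity statistics, closed-form model posteriors with marginal
    inclusion probabilities and model-averaged causal estimates,
    Q-statistic and Cook's-distance influence diagnostics with outlier
    removal, and a seeded generator of synthetic GWAS summary statistics
    for correlated exposures and imbalanced case-control outcomes.
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
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
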