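Package: mregger
Title: MR-Egger Regression and Summary-Data Mendelian Randomization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Summary-data Mendelian randomization with potentially invalid
    instruments. Implements the inverse-variance weighted (IVW) estimator and
    MR-Egger regression, whose unconstrained intercept estimates the average
    directional pleiotropic effect of the genetic variants and whose slope
    remains a consistent causal-effect estimate under the InSIDE assumption
    (instrument strength independent of direct effect). Includes per-variant
    Wald ratio estimates, Cochran's Q heterogeneity test, minor-allele-
    frequency corrected instrument strength, scatter and funnel diagnostics,
    a two-sample individual-level data simulator covering four pleiotropy
    scenarios, and a Monte Carlo study driver that tabulates bias, power and
    type-I error of both estimators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
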