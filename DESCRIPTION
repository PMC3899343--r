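Package: aphidRGR
Title: Modelling Cereal Aphid Relative Growth Rate from Field Counts,
    Temperature and Wheat Phenology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the instantaneous relative growth rate (RGR) of
    cereal aphid populations from noisy weekly field counts by taking the
    logarithmic derivative of a cross-validated cubic smoothing spline,
    and models the estimated RGR as a nonlinear response surface of mean
    temperature and Zadoks wheat growth stage, fitted by Gauss-Newton
    ordinary least squares.  Includes an optional linear extension for
    natural-enemy pressure (entomopathogenic fungus kills and parasitoid
    mummies), a full validation toolkit (ANOVA partition, Durbin-Watson
    autocorrelation test, bisector and origin-constrained R-squared,
    sign-error matrices, residual summaries), and a synthetic field-survey
    generator producing overdispersed aphid count series driven by
    simulated weather and degree-day wheat phenology, so the whole
    pipeline is testable without access to historical survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    e1071,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
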