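Package: siropop
Title: Population Pharmacokinetics and Initial Dose Optimization of
    Sirolimus in Pediatric Tuberous Sclerosis Complex
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Nonlinear mixed-effects modelling of sparse sirolimus trough
    concentrations from therapeutic drug monitoring in children with
    tuberous sclerosis complex, and Monte Carlo optimization of the
    initial dose against the 5-10 ng/ml trough window.  Implements a
    one-compartment oral model with fixed absorption and allometric
    weight scaling, lognormal inter-individual variability, additive /
    proportional / combined residual error, a Laplace-family (adaptive
    Gauss-Hermite, FOCE-style) marginal likelihood with OFV-based
    stepwise covariate selection, nonparametric bootstrap,
    goodness-of-fit residual diagnostics, prediction-corrected visual
    predictive checks, probability-of-target-attainment simulation over
    dose x weight x regimen x comedication scenarios, and a synthetic
    trough-cohort generator for validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    deSolve,
    withr
Config/testthat/edition: 3
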