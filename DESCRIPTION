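Package: fluxpls
Title: Hybrid Metabolic Flux Analysis with Partial Least Squares Productivity Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates intracellular metabolic fluxes from measured exchange
    rates by variance-weighted least squares over steady-state metabolite
    balances, including gross-error (consistency) testing against the
    chi-squared distribution, and chains the estimated fluxome to a measured
    productivity target through single-response partial least squares (PLS1)
    regression. Confidence intervals for the regression coefficients are
    obtained by Monte Carlo propagation of measurement errors, weakly
    associated fluxes are screened out with a strength-of-association filter,
    and the remaining fluxes are hierarchically clustered in the
    coefficient/confidence-interval plane. A synthetic-data generator
    produces steady-state culture datasets with known driver fluxes so the
    whole pipeline can be exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
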