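Package: seasonflow
Title: Species-Level Seasonality Analysis for Longitudinal Activated-Sludge Microbiomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for resolving annual seasonal dynamics of individual microbial
    species in longitudinal amplicon count tables from activated-sludge wastewater
    treatment plants. Provides sample quality control and replicate merging, robust
    centred log-ratio and Hellinger transforms, rarefied alpha diversity, weekly
    regularization of irregular time series, seasonal-trend decomposition with a
    periodic seasonal window, harmonic (cosinor) regression with peak-week
    confidence intervals, seasonal-strength scoring and seasonal-cohort
    assignment, growth-group classification from a steady-state immigration mass
    balance, cross-plant cohort comparison, and a synthetic-data generator with
    known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vegan,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    deSolve
Config/testthat/edition: 3
RoxygenNote: 7.3.3
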