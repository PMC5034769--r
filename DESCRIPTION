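Package: dynallo
Title: Dynamic Allometric Scaling and Biomass Distribution in Plants
Version: 0.1.0
Authors@R:
    person("dynallo", "developers", email = "dynallo@example.org",
           role = c("aut", "cre"))
Description: Statistical machinery for testing whether plant allometric
    scaling exponents are fixed or change continuously with size, and for
    quantifying lineage- and functional-group-level deviations in biomass
    distribution. Provides standardized major axis (model 2) and polynomial
    (model 1) fits of log-log organ mass relationships with BIC-based model
    selection; a binned central-difference estimator of the local scaling
    exponent with Loess smoothing and bootstrap confidence bands; biomass
    fraction (LMF/SMF/RMF) size trends; size-corrected percentile-rank
    statistics with species, family and functional-group summaries and
    variance partitioning; a demonstration of r-squared inflation in
    log-log regressions spanning many orders of magnitude; a minimal
    teleonomic growth model exhibiting dynamic exponents; and seeded
    synthetic-data generators for all of the above.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
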