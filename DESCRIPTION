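Package: urbancarbon
Title: Urban Forest Carbon Storage and Sequestration Accounting
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A national-scale urban forest carbon assessment pipeline for
    Canada. Derives ecozone-level carbon storage densities and gross
    sequestration rates (carbon per unit area of tree canopy) from
    city-level plot-based assessment summaries, scales them to
    province-by-ecozone reconciliation units through canopy cover using the
    IPCC Tier-2 gain equation, compares the result against a fixed-rate
    baseline, and propagates activity-data, sampling, and model
    uncertainties to percentile bounds with a three-class Monte Carlo
    scheme. Includes a point-grid canopy-cover estimator with the national
    survey's sampling design and quality-control rules, and synthetic-data
    generators (city assessments, reconciliation-unit tables, categorical
    landcover rasters) with known ground truth so every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
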