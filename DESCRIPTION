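Package: leadhazard
Title: Neighborhood-Level Lead Paint Hazard Scoring for Residential Parcels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores residential parcels for lead-based paint hazard from year
    built, appraised value, and building grade; aggregates parcel scores to
    census blocks, block groups, and tracts with a five-category risk
    classification; scores childcare centers by the normalized risk of parcels
    within a half-mile buffer; and cross-tabulates child population by race
    against risk tiers to quantify exposure and disparity. A seeded synthetic
    county generator emulates the auditor, census geography, child population,
    childcare, and opportunity-index inputs so the full pipeline runs and is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    tools,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
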