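Package: costream
Title: Techno-Economic and Energy Assessment of Fish Co-Stream Biorefineries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Declarative mass and energy balances, a co-digestion biogas/CHP
    model, a farm fertiliser balance, an annual cost/revenue/return-on-investment
    engine, and Monte Carlo price-uncertainty analysis for zero-waste processing
    of salmon filleting co-streams. Ships four reference processing concepts
    (direct anaerobic digestion, silage, thermal fractionation, two-stage
    thermal-enzymatic hydrolysis) as machine-readable scenarios, a synthetic
    scenario generator for property testing, and reporting utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
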