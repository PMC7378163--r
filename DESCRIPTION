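Package: kelpcarbon
Title: Continental-Scale Blue Carbon Accounting for Kelp Forests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Upscales plant- and plot-level kelp field measurements to
    per-hectare carbon density and net primary production, converts
    production to sequestration through a deep-export fraction, propagates
    uncertainty by the delta method and by Monte Carlo simulation,
    quantifies historical and projected habitat-loss impacts on carbon
    stocks and fluxes, and assembles a multi-ecosystem blue-carbon budget
    for vegetated coastal ecosystems. Includes a seeded synthetic field
    survey generator so the full pipeline is testable without external
    data.
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
    withr
Config/testthat/edition: 3
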