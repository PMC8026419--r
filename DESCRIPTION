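Package: tpaudit
Title: Textbook-Process Composite Quality Indicator Analysis for Hip Fracture Registries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores the all-or-none "textbook process" composite quality
    indicator for in-hospital hip fracture care (assessment of malnutrition,
    surgery within 24 hours, orthogeriatric management, operation by a
    certified trauma surgeon), benchmarks hospitals by case-mix adjusted
    observed/expected ratios with the indirect-standardization confidence
    interval for O = E, and models the association between textbook-process
    care and in-hospital outcomes (complications, prolonged stay, mortality).
    Ships a calibrated synthetic registry generator so every pipeline stage is
    testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
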