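Package: metshift
Title: Occupational Physical-Activity Trends and Energy-Balance Weight
    Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates secular trends in U.S. occupation-related physical
    activity energy expenditure from sector-level employment series and MET
    (metabolic equivalent) intensity assignments, and translates the
    expenditure decline into predicted population mean body weight with a
    single-compartment energy-balance differential equation model calibrated
    to published kg-per-kcal sensitivities. Includes a synthetic employment
    generator anchored to printed 1960/2008 sector prevalences, NHANES mean
    weight anchors for validation, ordinary least-squares trend tests, and an
    end-to-end reporting pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
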