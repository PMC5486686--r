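Package: fraxbuild
Title: Construction and Comparison of Country-Specific Fracture-Probability Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building a country-specific FRAX-style fracture
    probability model from regional hip-fracture registries: case
    ascertainment with registry exclusion rules (ICD-10 S72 codes,
    neoplasia, duplicate and prior-year admissions), age- and sex-banded
    incidence estimation with population-weighted amalgamation across
    catchments, piecewise log-linear smoothing of incidence with a fixed
    breakpoint, a competing-mortality hazard-integration engine producing
    10-year and remaining-lifetime probabilities of hip and major
    osteoporotic fracture under multiplicative clinical risk factors and
    femoral-neck BMD, and machinery for comparing two such models over
    exhaustive clinical-scenario grids (piecewise regression, percentile
    tables with tolerance intervals, correlations). Includes a synthetic
    registry generator with planted exclusions and known ground truth so
    the whole pipeline is testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
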