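Package: shellforage
Title: Two-Island Comparisons of Stone-Tool Foraging Pressure on Intertidal Shellfish
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for comparing tool-assisted shellfish foraging between a
    high-predation and a low-predation island population: typed CSV survey
    tables with the field protocol's record-level filters, a synthetic-data
    generator emulating the study design, cluster-level permutation tests,
    percentile-bootstrap group comparisons, random-intercept mixed models
    with likelihood-ratio tests and leave-one-out stability diagnostics,
    quadrat and point-transect density estimation, and a
    consumption-extrapolation depletion model with a life-history
    vulnerability assessment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    lme4,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
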