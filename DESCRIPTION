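Package: liprisk
Title: Exposure and Health-Risk Assessment of Trace Lead in Lip Cosmetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing oral-ingestion exposure to trace lead (Pb)
    measured in lip cosmetics (lipsticks, lip glosses, lip balms). Implements
    the deterministic USEPA ingestion pathway (average daily dose, hazard
    quotient, incremental lifetime cancer risk), seeded Monte Carlo
    propagation of a zero-inflated lognormal concentration distribution fitted
    to panels with heavy non-detect fractions, the Adult Lead Methodology
    (ALM) blood-lead model with maternal-fetal transfer scenarios, a
    simplified multi-media child Pb intake/uptake calculator, and a synthetic
    concentration-panel generator for fully reproducible end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
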