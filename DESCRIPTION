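Package: labmeld
Title: Quality-Assured Laboratory MELD Score Computation and Verification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the laboratory Model of End-stage Liver Disease (MELD)
    and MELD-Na scores with the regulatory clamps and the dialysis creatinine
    override, and screens every MELD request through a laboratory verification
    rule engine covering order integrity, preanalytical quality, dialysis
    plausibility, anticoagulation influence on the INR, delta checks against
    prior results, and undeterminable clotting tests. Each request receives a
    machine-readable verdict (valid, corrected-valid, invalid, or
    needs-consultation) with ordered reason codes. A seeded cohort simulator
    with calibrated per-category error injection makes the whole pipeline
    testable end to end without patient data, and reporting helpers summarise
    cohorts and render Eurotransplant-style result documents.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
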