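Package: ribpet
Title: Range Verification and Washout Kinetics for Radioactive Ion Beam PET
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for preclinical radiotherapy with radioactive
    ion beams monitored by in-beam positron emission tomography (PET).
    Implements the mixed positron-emitter physical decay model of a C-11
    beam, double-exponential biological washout kinetics with nested F-test
    model selection, analytic Bragg-curve and spread-out Bragg peak (SOBP)
    construction, depth-profile range-verification metrics (beam's-eye-view
    integration, 80% distal fall-off, activity peak alignment), tumour
    growth volumetrics and grip-strength toxicity statistics, together with
    a fully seeded synthetic cohort generator that emulates the statistical
    structure of such a study end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    pracma,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
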