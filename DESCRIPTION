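Package: inflamdiet
Title: Dietary Inflammatory Index and Antioxidant Capacity Scoring for
    Case-Control Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes the energy-adjusted Dietary Inflammatory Index
    (E-DII) from food-frequency-questionnaire nutrient intakes, total
    dietary non-enzymatic antioxidant capacity (NEAC) on the Trolox
    equivalent (TEAC) scale from food-item gram intakes, and a combined
    inflammatory-antioxidant profile score built from control-based
    quartiles.  Provides unconditional logistic regression machinery for
    case-control odds ratios with trend tests, likelihood-ratio
    interaction tests, stratified and sensitivity analyses, and a
    synthetic FFQ-study generator with planted effects for validating
    every stage of the pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    tools,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
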