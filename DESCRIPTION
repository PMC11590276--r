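Package: ckdcost
Title: Bottom-Up Matched-Control Costing of Chronic Kidney Disease from Linked Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for estimating direct healthcare costs attributable to
    chronic kidney disease (CKD) from linked person-level administrative records.
    Implements longitudinal KDIGO CKD staging from dated laboratory results
    (CKD-EPI eGFR, urine albumin-creatinine ratio chronicity, dialysis-code
    overrides), 1:1 exact matching of cases to non-CKD controls with ordered
    constraint relaxation, component-wise bottom-up costing of hospital,
    emergency, medication, primary-care and pathology utilisation under
    Australian pricing conventions (AR-DRG unit costs, PBS tier-weighted
    medication prices, MBS pathology coning), gamma log-link generalised linear
    models for transferring modelled cost components across datasets,
    case-minus-control attributable cost aggregation by stage and person-year,
    and extrapolation of stratum-specific rates and costs to a national
    population, including an undiagnosed early-stage adjustment. A synthetic
    linked-data generator with configurable stage prevalence, diabetes-by-stage
    confounding and stage-dependent cost distributions makes every step testable
    end-to-end without access to restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
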