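Package: repscreen
Title: Signature-Reversal Drug Repurposing Screens with EHR-Based
    Clinical Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for a two-stage drug-repurposing workflow. Stage one
    builds disease gene-expression signatures from genetically imputed
    differential-expression tables (top-K and FDR selection rules) and
    screens a drug-perturbation library for compounds whose expression
    changes reverse the disease signature (negative weighted Pearson
    correlation). Stage two validates candidate drugs in longitudinal
    electronic-health-record data with a self-controlled case-series
    design: per-person baseline and treatment observation windows, an
    exclusion cascade with attrition accounting, per-period median
    biomarkers, and a paired linear mixed model with a per-person random
    intercept. A synthetic-data generator produces DEG tables,
    perturbation libraries with planted reversers, and longitudinal EHR
    extracts with known injected treatment effects, so the whole
    pipeline is testable end to end without access to restricted
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
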