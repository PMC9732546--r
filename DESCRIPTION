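Package: pdxefficacy
Title: Preclinical PDX Efficacy, Response Classification and RT-qPCR
    Pharmacodynamics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for preclinical patient-derived xenograft
    (PDX) drug-efficacy studies. Converts caliper measurements into tumor
    volumes and relative tumor volumes (RTV), computes arm-level tumor
    growth inhibition (TGI) with the 50% meaningful-effect rule, classifies
    per-mouse response via relative tumor variation (RTVV) and the overall
    response rate (ORR < -0.5 responder cut-off), derives RTV-fold
    (doubling and quadrupling) progression events for Kaplan-Meier and
    Mantel-Cox log-rank comparison, and quantifies RT-qPCR
    pharmacodynamics by the 2^deltaCt method with dual human/murine TBP
    referencing and basal normalization at Ct = 35. Exact two-tailed
    Mann-Whitney U and Fisher tests are implemented for the small arm
    sizes (4-7 mice) typical of PDX trials. A synthetic-cohort generator
    reproduces the study design (exponential growth with lognormal rate
    heterogeneity, enrollment at 60-150 mm3, weekly caliper measurement,
    sacrifice near 500 mm3) so every pipeline stage is testable without
    animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
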