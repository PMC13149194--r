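Package: survcua
Title: Cost-Utility Analysis of Oncology Treatments from Reconstructed Survival Curves
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A cohort-level cost-utility modelling pipeline for two-arm oncology
    comparisons built on published Kaplan-Meier evidence. Reconstructs pseudo
    individual patient data from digitized survival coordinates and
    number-at-risk tables, extrapolates progression-free and overall survival
    with standard parametric and fractional-polynomial hazard models selected
    by information criteria, simulates a three-state (progression-free,
    progressed, dead) cohort under either a Markov state-transition or a
    partitioned-survival structure, and attaches discounted costs and
    quality-adjusted life-years to produce incremental cost-effectiveness
    ratios. Includes one-way deterministic and probabilistic sensitivity
    analyses with cost-effectiveness acceptability curves, price-threshold
    search against willingness-to-pay levels, patient-assistance-program and
    subgroup scenarios, and a synthetic two-arm trial generator so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    survival,
    flexsurv
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
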