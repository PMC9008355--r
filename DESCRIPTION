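Package: psmcea
Title: Partitioned Survival Cost-Effectiveness Modelling of First-Line
    Therapy for Advanced Hepatocellular Carcinoma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A three-state (progression-free, progressed, dead) partitioned
    survival model for cost-effectiveness analysis of donafenib versus
    sorafenib as first-line treatment of unresectable or metastatic
    hepatocellular carcinoma from a Chinese healthcare payer perspective.
    Provides pseudo individual-patient-data reconstruction from digitized
    Kaplan-Meier curves with numbers at risk (the Guyot algorithm),
    maximum-likelihood fitting and information-criterion selection among six
    parametric survival families, discounted cost and QALY accrual with
    incremental cost-effectiveness ratios, one-way deterministic and
    probabilistic sensitivity analysis with Cholesky-correlated survival
    parameters, cost-effectiveness acceptability curves, scenario analyses,
    and seeded synthetic-data generators emulating digitized trial curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    flexsurv,
    survival,
    stats,
    utils,
    yaml
Suggests:
    ggplot2,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
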