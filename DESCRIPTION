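Package: esaCEA
Title: Cost-Effectiveness Analysis of Erythropoiesis-Stimulating Agents in
    Chronic Haemodialysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Decision-analytic cost-effectiveness analysis of once-monthly
    continuous erythropoiesis receptor activator (CERA) versus thrice-weekly
    epoetin beta for anaemia management in chronic haemodialysis patients.
    Implements clinical-success-rate effectiveness from monthly haemoglobin
    trajectories, drug-acquisition costing with currency conversion and
    discounting, two-arm decision-tree rollback, average and incremental
    cost-effectiveness ratios with dominance and willingness-to-pay threshold
    decisions, deterministic one-way and two-way sensitivity analysis, and
    Monte Carlo probabilistic sensitivity analysis with cost-effectiveness
    plane and acceptability-curve summaries. Includes a dose-titration
    protocol simulator that generates synthetic two-phase patient cohorts for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
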