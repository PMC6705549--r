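Package: oralcea
Title: Cost-Effectiveness Modelling of Oral Rehabilitation Strategies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A cohort Markov state-transition engine for decision-analytic
    cost-effectiveness evaluation of prosthetic rehabilitation of mandibular
    edentulism. Implements annual-cycle cohort propagation with discounting,
    quality-adjusted prosthesis year (QAPY) effectiveness accrual, scheduled
    prosthesis-replacement costing, deterministic incremental
    cost-effectiveness ratios (ICER) with dominance classification and net
    monetary benefit, probabilistic sensitivity analysis with
    Dirichlet/Gamma/Beta parameter uncertainty, cost-effectiveness planes and
    acceptability curves, plus an individual-level microsimulation oracle and
    random-scenario generator for validation. Ships a fully parameterized
    scenario comparing two-implant mandibular overdentures with conventional
    complete dentures from the perspective of the Brazilian Unified Health
    System (SUS), costed from the 2018 SIGTAP tariff table.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
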