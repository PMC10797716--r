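Package: tiocue
Title: Markov Cohort Cost-Utility Model of Add-On Tiotropium in Severe Asthma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Probabilistic Markov cohort model for the cost-utility of add-on
    tiotropium versus inhaled corticosteroids plus long-acting beta2-agonists
    (ICS+LABA) in adults with severe uncontrolled asthma. Provides a
    two-week-cycle cohort engine with background mortality from a life table,
    exacerbation event channels (oral corticosteroid burst, emergency
    department visit, hospitalization), treatment-effect application on the
    exacerbation rate, adherence waning, discounted lifetime costs and
    quality-adjusted life-years with half-cycle correction, probabilistic
    sensitivity analysis by second-order Monte Carlo with beta/gamma
    method-of-moments parameter distributions, net-monetary-benefit decision
    statistics, cost-effectiveness acceptability curves, and one-way
    deterministic sensitivity analysis with tornado ordering. A synthetic
    Makeham life-table generator supplies background mortality so no external
    data are required.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    optparse
Config/testthat/edition: 3
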