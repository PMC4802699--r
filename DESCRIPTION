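Package: tdmcost
Title: Discrete-Event Cost Simulation of Test-Based Versus Empirical
    Anti-TNF Dose Escalation in Crohn's Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Patient-level discrete-event simulation comparing the direct
    anti-TNF drug cost of two management strategies for Crohn's disease
    patients losing response to infliximab: empirical dose escalation
    (dose doubling, interval shortening, immunosuppressant combination,
    switch to adalimumab, weekly adalimumab) versus a pharmacokinetic
    test-based strategy in which trough levels and anti-drug antibodies
    route patients to dose optimization, in-class switch, or exit from
    the anti-TNF class. Includes per-consultation event sampling on a
    weekly clock, uniform sensitivity draws of event probabilities,
    euro-cent cost accounting with an optional surgery and post-operative
    infliximab extension, cohort comparison across 1-, 3- and 5-year
    horizons, and a bootstrap of simulation-level mean savings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
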