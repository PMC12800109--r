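Package: amtcea
Title: Cost-Utility and Financial Impact Modelling of Digital Anemia
    Management in Hemodialysis
Version: 1.0.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A Markov cohort cost-utility model for evaluating a digital
    avatar-based anemia management tool (AMT) in adult in-center
    hemodialysis patients from the US Medicare perspective.  Implements
    the evidence-synthesis chain that translates a reduction in
    intrapatient hemoglobin variability into mortality and
    hospitalization effects (Chinn standardized-mean-difference scaling
    and odds-ratio to relative-risk conversion), a two-state
    (alive/dead) life-table cohort engine with half-cycle correction and
    mid-cycle discounting, net-monetary-benefit and ICER calculators, a
    provider-perspective net financial impact analysis (ESA savings,
    Quality Incentive Program revenue, implementation costs), a
    payer-perspective budget impact analysis, and deterministic
    (tornado) plus probabilistic (Monte Carlo) sensitivity analyses with
    Beta-PERT, lognormal, beta, gamma, uniform and normal parameter
    distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
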