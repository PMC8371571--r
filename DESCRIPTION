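Package: ugiscreen
Title: Markov Cohort Cost-Effectiveness Model for Combined Endoscopic
    Screening of Esophageal and Gastric Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A 26-state Markov cohort model of esophageal and gastric cancer
    progression in high-risk areas of China, used to evaluate the
    cost-effectiveness of combined endoscopic screening strategies
    (once per lifetime through every 2 years) against no screening.
    Provides the closed-cohort simulation engine with half-cycle
    correction and discounting, incremental cost-effectiveness ratio
    (ICER) and efficiency-frontier analysis against WHO GDP-multiple
    thresholds, grouped one-way sensitivity sweeps, and probabilistic
    sensitivity analysis with cost-effectiveness acceptability curves,
    together with a synthetic-parameter generator that emulates the
    supplement-only model inputs (transition matrix, initial prevalence,
    background life table) so the whole pipeline runs self-contained.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
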