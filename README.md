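# ugiscreen

A Markov cohort model for the cost-effectiveness of **combined endoscopic
screening for esophageal cancer (EC) and gastric cancer (GC)** in
high-risk areas of China, written for health-economics analysts and
screening-program modelers.

## What it models

A closed cohort of 100 000 people enters at a band mean age (42, 47, 52,
57, 62 or 67 years) and is followed in 1-year cycles until mean age 90
through a 26-state progression graph: `normal`, `death`, nine
organ-specific lesion/cancer stages (EC: mild → moderate → severe
dysplasia/CIS → early → advanced cancer; GC: LGIN → HGIN/CIS → early →
advanced cancer) each split into *undetected*/*detected*, plus six
*posttreatment* states. Five screening strategies (once per lifetime;
every 10, 5, 3, 2 years; eligibility ages 40–69) are compared with no
screening.

Each cycle applies a screening round (compliance 0.49; sensitivity /
specificity 0.96/0.90 for EC and 0.89/1.00 for GC; complications at
0.00009 per examination), self-initiated examination (annual
probabilities 0.01 / 0.20 / 0.70 for severe lesions / early / advanced
cancer), stage-specific treatment compliance, then natural-history
transitions with age-specific background mortality. Rewards use the
trapezoidal half-cycle correction and mid-cycle discounting at 5%/year.

For strategies *s* with discounted totals (QALY<sub>s</sub>,
Cost<sub>s</sub>), the package computes

> ICER = ΔCost / ΔQALY,

both versus no screening and versus the next most effective strategy
(sequential comparison, as well as a proper efficiency-frontier mode
with extended dominance), classified against the WHO thresholds at 1×
and 3× the 2019 Chinese per-capita GDP (US$10 276). Uncertainty is
handled by grouped one-way sweeps over the published ranges and by
probabilistic sensitivity analysis (triangular/beta/gamma parameter
distributions, net-monetary-benefit acceptability curves).

Supplement-only inputs (transition probabilities, baseline prevalence,
life table) are emulated by a seeded synthetic generator; a loader
accepts real parameter bundles in the same YAML + CSV schema. See the
methods vignette (`vignettes/ugic-screening-model.Rmd`) for the model
assumptions and every default.

## Worked example

```r
library(ugiscreen)

pset   <- synthetic_parameter_set(seed = 1)   # synthetic stand-in inputs
config <- run_config(pset, ages = 62, out_dir = tempdir())
tab    <- cmd_run(config, write = FALSE)
tab[, c("age_band", "strategy", "qalys", "cost_thousand",
        "icer_vs_none", "icer_vs_next")]
#>   age_band          strategy   qalys cost_thousand icer_vs_none icer_vs_next
#> 1    60-64      no_screening 1150357      27025.20           NA           NA
#> 2    60-64 once_per_lifetime 1152340      34937.28         3990         3990
#> 3    60-64          every_5y 1153318      39921.40         4355         5097
#> 4    60-64          every_3y 1153950      43744.49         4654         6052
#> 5    60-64          every_2y 1154367      46889.91         4954         7544

who_category(tab$icer_vs_next[-1])
#> [1] "highly cost-effective" "highly cost-effective" "highly cost-effective"
#> [4] "highly cost-effective"
```

Reading: at entry age 60–64 the every-10-years row is absent because its
schedule coincides with once-per-lifetime under the 40–69 eligibility
window. On this synthetic parameterization every strategy gains QALYs
over no screening, each step up in frequency costs more per QALY, and
all ICERs stay below the per-capita GDP — the qualitative pattern of the
published analysis (absolute totals differ because the natural-history
inputs are synthetic stand-ins, flagged as such in the output
provenance header).

`cmd_oneway()`, `cmd_psa()`, `cmd_frontier()` and `cmd_synth()` produce
the tornado, CEAC, frontier and parameter-bundle CSVs; a thin CLI
wrapper lives at `inst/cli/ugiscreen`.

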