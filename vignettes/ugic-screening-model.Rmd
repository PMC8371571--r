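---
title: "A Markov cohort model for combined endoscopic EC/GC screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov cohort model for combined endoscopic EC/GC screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ugiscreen)
```

## The decision problem

Upper gastrointestinal tract cancer — esophageal cancer (EC) and gastric
cancer (GC) — is concentrated in identifiable high-risk areas of China,
where both cancers progress through long precancerous phases that
endoscopy can detect and treat. `ugiscreen` implements a state-transition
(Markov) cohort model for evaluating population endoscopic screening
offered to residents aged 40–69: five active strategies (once per
lifetime; every 10, 5, 3 or 2 years) against no screening, for closed
cohorts of 100 000 entering at mean age 42, 47, 52, 57, 62 or 67 and
followed in 1-year cycles until the mean age reaches 90.

## Health states

The model has 26 states:

* `normal` and `death`;
* nine organ-specific lesion/cancer stages — the EC chain (mild
  dysplasia → moderate dysplasia → severe dysplasia/CIS → early cancer →
  advanced cancer) and the GC chain (LGIN → HGIN/CIS → early cancer →
  advanced cancer) — each split into an *undetected* and a *detected*
  state (18 states);
* six *posttreatment* states, one per treatable stage and organ (severe
  dysplasia/CIS or HGIN/CIS, early cancer, advanced cancer).

This 2 + 18 + 6 decomposition is the unique one consistent with every
progression state carrying a detection flag plus a separate
posttreatment tier for the treated stages. Because the published state
diagram itself sits in supplementary material we could not bundle, the
builder (`build_state_space()`) is configurable: chains can be dropped
and the treatable set changed, so a differently documented structure can
replace the default. States are mutually exclusive — synchronous EC and
GC lesions in one person are not modeled, as a cohort-level Markov model
requires exclusive states and dual-primary disease is rare.

One genuinely open choice: whether screen-detected mild/moderate
dysplasia and LGIN occupy distinct "under surveillance" states or reuse
the undetected states with a flag. We use distinct detected states (they
are part of the 18), which keeps detection irreversible — a rule
`validate_matrix()` enforces (no transition from any detected or
posttreatment state back to an undetected state) along with
row-stochasticity and an absorbing death state.

## Within-cycle event order

The source analysis does not state an event order; ours is

1. **screening round** (only at offered cycles),
2. **self-initiated examination** (every cycle),
3. **treatment offer** to newly diagnosed mass,
4. **surveillance reexamination** costs,
5. **natural-history transition** with background mortality overlaid.

This ordering guarantees that a detection and its treatment fall in the
same cycle, matching the definition of treatment compliance as the
proportion of screened patients completing the entire treatment
procedure.

A screening round invites everyone in `normal` or an undetected state
(people already diagnosed or treated are in care and not re-invited);
49% attend. Attendees with a lesion are detected with the organ-specific
sensitivity (0.96 EC, 0.89 GC); attendees free of a lesion in one organ
generate a false positive for it at one minus its specificity (0.90 EC,
1.00 GC), each costing one reexamination endoscopy and a small QALY loss
(default 0.001 per event — the loss of quality of life from a false
positive is asserted in the source but unquantified, so the decrement is
configurable). Complications accrue at 0.00009 per attendee.
Mobilization/administration ($1.05) is charged per *invited* person and
the examination cost ($47.87) per *attendee*, following the two cost
labels.

Undetected severe dysplasia/CIS and HGIN/CIS, early cancer and advanced
cancer also surface through self-initiated examination at annual
probabilities 0.01, 0.20 and 0.70; milder lesions are asymptomatic and
never self-detect.

Newly diagnosed mass in a treatable stage is offered treatment once: the
stage-specific compliant fraction (e.g. 0.9405 for early EC, 0.5455 for
HGIN/CIS) moves to the posttreatment state and pays the stage's initial
treatment cost; decliners stay detected-untreated and keep the stage's
natural history (detection without treatment does not alter disease
course). Mass that *progresses* into a treatable detected state — a
surveillance patient progressing, or a posttreatment recurrence — is
treated as a new clinical event and re-offered treatment the following
cycle.

Screen-detected mild/moderate dysplasia and LGIN stay under endoscopic
surveillance: the reexamination-compliant fraction (0.67) incurs one
endoscopy cost per year, and their progression is assumed caught (they
progress within the detected tier). The non-compliant fraction is
approximated the same way; this is forced by the irreversible-detection
rule and slightly favors surveillance, a known simplification.

## Rewards, discounting, half-cycle correction

QALYs weight occupancy by stage-level utilities (normal 1, death 0;
e.g. 0.70 early EC, 0.57 advanced GC); posttreatment and
detected-untreated states keep their stage's utility, since the
published utilities are stage-level. Annual health-care costs accrue in
detected cancer/precancer states of treatable stages and in
posttreatment states, for as long as the person stays there (a lifetime
accrual; a fixed follow-up window can be configured by zeroing the cost).

State rewards use the trapezoidal half-cycle correction — the mean of
start- and end-of-cycle occupancy — which reduces to the exact
person-time identity for constant occupancy. One-time event costs and
disutilities are discounted at mid-cycle, `(1+r)^-(t+0.5)`, consistent
with events spread through the cycle; start-of-cycle timing is available
via `event_timing = "start"` because decision-tree software defaults
differ between versions and the source does not say which was used.
Both QALYs and costs are discounted at 5%/year (range 0–8%).

Cancer-specific mortality applies only in advanced states and is derived
from 5-year survival as `1 - S^(1/5)` (`annual_prob_from_survival()`).
Background mortality is overlaid per cycle from an age-indexed life
table by proportional rescaling of each living row.

## Cost-effectiveness analysis

`icer()` computes incremental cost per QALY with dominance flags.
`frontier_sequence()` orders strategies by effectiveness and compares
each with its predecessor. The default mode is the *sequential*
next-most-effective comparison with **no** extended-dominance pruning:
the published base-case table reports a non-monotone ICER sequence
(3035 then 1087 in the youngest band), which proves no pruning was
applied there. A standard `"frontier"` mode (strong then extended
dominance removed, ICERs strictly increasing) is provided for general
use. `who_category()` classifies ICERs against 1× and 3× the 2019
per-capita GDP (US$10 276). ICERs are reported rounded to whole dollars;
increments are carried at full precision internally.

## Uncertainty analysis

Every published parameter carries a range and a distribution:
triangular (min, mode, max) for compliances, test characteristics,
self-examination and the surveillance-tier utilities; beta for treatment
compliances and disease-state utilities; gamma for costs, read as
(shape, rate) — under the (shape, scale) reading the means are wildly
inconsistent with the base cases (e.g. mobilization γ(0.16, 0.15) has
mean 1.07 ≈ $1.05 as a rate, 0.024 as a scale). Four of the
initial-treatment gammas are printed in units of 10⁴ US$; a
power-of-ten unit scale reconciling each gamma mean with its base case
is inferred at load and applied to draws. After scaling, printed-rate
rounding leaves one distribution mean ~12% from its base case, so the
load-time consistency check warns beyond 20% rather than failing.

One-way sweeps (`one_way_sweep()`) move a parameter group to its low
limit, then its high limit, re-running the model each time. Grouped
parameters (the nine utility scores; the three screening-cost
components; the baseline prevalences) move on a common quantile — both
at low or both at high — realizing the stated positive correlation
without a joint copula. Cost ranges are ±50% of base.

The PSA (`run_psa()`) samples all uncertain parameters jointly once per
draw and evaluates every strategy on the common draw (common random
numbers); the discount rate stays fixed. Draws are clamped to semantic
domains ([0, 1] for probabilities and utilities) but not truncated to
the printed ranges, since truncation is not documented; it can be added
by editing a spec's `domain`. Acceptability curves use net monetary
benefit `WTP × QALYs − cost`, on a default WTP grid of 0 to 3× GDP in
100 steps; `ceac_vs_comparator()` gives the probability of beating no
screening and `prob_optimal()` the probability of maximizing NMB, with
ties split equally so probabilities partition the draws.

## The synthetic parameter generator

The published analysis rests on several supplement-only inputs we could
not bundle: the baseline prevalence table, the annual transition
probabilities, the treatment/cost derivation tables, and the yearbook
life table. `synthetic_parameter_set()` generates internally consistent
stand-ins so every pipeline stage runs self-contained:

* **Transition rates** — entry to mild dysplasia/LGIN at 0.8–1.0% per
  year; stepwise progression (6–7% between dysplasia grades, 5–6% in the
  GC chain, 30%/25% early→advanced) with regression between adjacent
  precancer states; recurrence 2–10% per year from posttreatment;
  advanced-cancer mortality from 5-year survival of 15% (EC) and 20%
  (GC) untreated, 35%/40% after treatment. Values were fixed once from
  the span of natural-history estimates in the EC/GC screening
  literature and are *not* calibrated to reproduce the published
  absolute QALY/cost totals (deliberately out of scope).
* **Baseline prevalence** — per 100 000 aged 40+: 6 000 mild and 1 500
  moderate dysplasia, 500 severe/CIS, 150 early and 50 advanced EC;
  8 000 LGIN, 300 HGIN/CIS, 200 early and 50 advanced GC; all
  undetected at baseline.
* **Life table** — a Gompertz-type hazard `level·exp(slope·(age−40))`
  with level 0.002 and slope 0.085, giving q(40) ≈ 0.002 rising to
  q(90) ≈ 0.12, a plausible adult mortality curve.

A seeded log-normal jitter (SD 0.05) individualizes a generated set;
generation is deterministic given the seed. Every generated matrix must
pass `validate_matrix()`. The bundle is written as YAML + CSV by
`write_parameter_set()`, and `read_parameter_set()` accepts a directory
in the same schema — so supplement-derived values, where available, drop
in verbatim. Output metadata records the provenance (`published` vs
`synthetic`) of every block so synthetic numbers cannot be mistaken for
reproductions.

What the synthetic set does and does not show: passing tests demonstrate
the *mechanics* — mass conservation, detection/treatment bookkeeping,
discounting arithmetic, ICER and PSA machinery, and agreement with an
independent individual-level microsimulation. They do not validate the
natural-history inputs against surveillance data, and absolute QALY and
cost totals under the synthetic set differ from the published ones by
construction. The published ICER *arithmetic* (ratios from printed
increments) is reproduced exactly from the bundled reference table.

## Numerical choices and problem sizes

* Row-stochasticity tolerance 1e-9; cohort mass conservation asserted to
  1e-6 per cycle.
* QALY ties in frontier construction are broken by cost and flagged.
* NMB ties in `prob_optimal()` use a 1e-12 comparison slack.
* Unit tests run cohorts of 2 000–100 000 over shortened horizons where
  only structure is at stake; the oracle comparison uses the full
  48-cycle horizon with a 20 000-person microsimulation and a 3-standard-
  error band; PSA tests use 4–20 draws since determinism and bounds, not
  Monte-Carlo precision, are under test.

## Known limitations

* One mean age per band; no within-band age heterogeneity, no tunnel
  states for minimum stage dwell times, no age dependence in the
  precancer transition rates (the source notes the same limitation).
* Screening compliance is independent across rounds; real-world
  compliance decays with frequency.
* Surveillance non-compliance does not delay detection of progression
  (see above).
* Societal costs (productivity, travel) are excluded — the perspective
  is the health care system.
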