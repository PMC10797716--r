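---
title: "Model methods: Markov cohort cost-utility of add-on tiotropium in severe asthma"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tiocue)
```

## The decision problem

Adults with severe asthma that stays uncontrolled on medium/high-dose
inhaled corticosteroids plus a long-acting beta2-agonist (ICS+LABA) can
receive add-on tiotropium, a long-acting muscarinic antagonist. The add-on
reduces the exacerbation rate (relative risk 0.72, 95% CI 0.62–0.83) but
adds a recurring drug cost. `tiocue` implements a probabilistic Markov
cohort model that weighs these against each other in lifetime discounted
costs (2023 US$) and quality-adjusted life-years (QALYs), and evaluates
cost-effectiveness at a willingness-to-pay (WTP) threshold of US$5,180 per
QALY.

## Model structure

The cohort model runs on a two-week cycle. Alive patients occupy a single
chronic "controlled/uncontrolled on maintenance therapy" state; death is
absorbing. Exacerbations are modelled as *within-cycle transient events*
layered on the alive state, in three severity channels: OCS burst
(outpatient oral corticosteroid course), emergency-department (ED) visit,
and hospitalization. A two-week cycle matches the length of an
exacerbation episode, so an event occupies one cycle's person-time and
tunnel states are unnecessary; utilities enter as per-event decrements,
which is the natural pairing for an event (rather than state) formulation.
This formulation is a declared design choice of the package.

Within a cycle, competing risks are resolved in a fixed, documented order:

1. background all-cause death, with per-cycle probability
   `annual_q_to_cycle_q(qx(age), 14)` from the life table (age advances by
   14/365.25 years per cycle; `qx` is looked up by completed integer age);
2. survivors experience at most one exacerbation; each channel's
   probability is `1 - exp(-split_i * rate * 14/365.25)` (probabilities are
   renormalized, with a warning, in the pathological case their sum exceeds
   1);
3. hospitalized patients die of asthma with the case-fatality probability
   (default 0.01 per hospitalization; OCS/ED episodes carry no excess
   mortality).

The treatment effect applies on the *rate* scale before the probability
conversion: the add-on arm's exacerbation rate is `rate * RR` while on
treatment.

### Adherence waning

28% of add-on patients discontinue after 16 weeks (cycle 8 on the two-week
grid). The engine runs two sub-cohorts — fully adherent, and reverting to
comparator inputs (losing both the relative risk and the drug cost) from
cycle 8 — and blends them with weights 0.72/0.28 (`blend_adherence()`).
The blend is the occupancy-weighted mixture, identical in expectation to
an individual-level simulation in which each patient is a discontinuer
with probability 0.28, which is exactly what the test oracle
(`oracle_simulate()`) verifies. The printed adherence figure of 61%
(76%/57%) conflicts with the 28%-at-16-weeks mechanism; the mechanism is
the more operational statement and is used for the base case, while
1 − adherence (0.24–0.43) supplies the sensitivity range on the
discontinuation fraction.

## Parameters and distributions

The packaged base case (see
`system.file("extdata", "table1_parameters.yaml", package = "tiocue")`,
returned by `table1_fixture()`):

| Parameter | Base | Range | PSA family |
|---|---|---|---|
| Tiotropium cost per 4 weeks (US$) | 71 | 53–89 | gamma |
| Controlled-state annual cost (US$) | 38 | 28–47 | gamma |
| OCS-burst episode cost (US$) | 38 | 28–47 | gamma |
| ED-visit episode cost (US$) | 2648 | 1986–3310 | gamma |
| Hospitalization episode cost (US$) | 230 | 173–288 | gamma |
| Controlled-state utility | 0.74 | 0.56–0.93 | beta |
| Decrement, OCS burst | 0.10 | 0.08–0.13 | beta |
| Decrement, ED visit | 0.15 | 0.11–0.19 | beta |
| Decrement, hospitalization | 0.20 | 0.15–0.25 | beta |
| Relative risk on exacerbation rate | 0.72 | 0.62–0.83 | beta |
| Exacerbation rate (events/yr) | 1.14 | 0.855–1.425 | beta (on cycle probability) |
| Discontinuation fraction | 0.28 | 0.24–0.43 | beta |
| Annual discount rate | 0.05 | 0–0.06 | fixed in PSA |

Ranges are treated uniformly as 95% intervals: `sd = (upper - lower)/3.92`.
For the relative risk the range *is* a published 95% CI; the other ranges
follow the ±25% convention of the source material, and one conversion rule
keeps the probabilistic analysis construction uniform. Distributions are
fitted by the method of moments (`beta_from_mean_range()`,
`gamma_from_mean_range()`), so every fit reproduces its mean exactly and
its sd to numerical precision; degenerate ranges become fixed values. A
beta distribution cannot carry an annual rate above 1, so the exacerbation
rate is sampled as its per-cycle transition probability (0.0428 at base),
fitted beta on that scale and converted back — this also keeps every
sampled transition probability in [0, 1] by construction. Sampling is
mean-preserving on the probability scale (the scale the engine consumes).
A user-supplied relative risk with range reaching 1 falls back to a
log-normal fit with a warning, since the beta support ends at 1.

Quantities the source material never publishes are shipped as explicit,
validated, configurable assumptions: the severity split of the
exacerbation rate (0.40 OCS / 0.35 ED / 0.25 hospitalization) and the
asthma case fatality per hospitalization (0.01). Both are held fixed in
PSA and DSA because no ranges exist for them. The cost figures are encoded
exactly as printed in the source table, including the ED episode cost
(2648) exceeding the hospitalization episode cost (230); the package
treats the printed table as authoritative rather than silently "fixing"
it.

## Outcomes

Per-cycle rewards (`cycle_rewards()`):

* cost = alive·(annual state cost)·14/365.25 + Σ incidence_i·episode
  cost_i + on-treatment alive mass·(drug cost per 4 weeks)·14/28;
* QALY = [alive·utility − Σ incidence_i·decrement_i]·14/365.25, i.e. each
  decrement applies for exactly one cycle's person-time (episodes are
  defined as lasting about a week, so one two-week cycle bounds them); a
  negative cycle QALY is clamped at zero with a warning.

Totals use half-cycle correction as trapezoidal end-weights (½, 1, …, 1,
½) and per-cycle discounting `(1+r)^(-cycle·14/365.25)` at r = 5%/year
(`accumulate_strategy()`). Decision statistics follow the standard
definitions: ICER = ΔC/ΔE with an explicit cost-effectiveness-plane
quadrant label (a negative ICER alone is ambiguous), and net monetary
benefit NMB = QALY·λ − cost with the effects-scale companion NMB/λ.

## Uncertainty analysis

`run_psa()` performs second-order Monte Carlo: each draw samples one joint
parameter set (independent parameters, common to both strategies within
the draw — sampling the arms independently would inflate the incremental
variance), runs both cohorts, and records the four discounted totals. The
default is 10,000 draws; draws are generated parameter-set-by-parameter-set
so draw *i* is reproducible from the seed alone. `summarize_psa()` reports
means, 2.5th/97.5th empirical centiles (linear-interpolation quantiles,
fixed by declaration for reproducibility), P(cost saving) = P(ΔC<0),
P(more effective) = P(ΔE>0), and P(cost-effective) computed by the same
expression the CEAC uses, `λΔE − ΔC > 0`, so the summary probability and
`ceac()` at λ agree exactly. The CEAC grid default is 0–15,540 (three
times the threshold) in 101 points. `one_way_dsa()` varies each of the 13
ranged parameters to its bounds with everything else at base, and orders
bars by |NMB(high) − NMB(low)|.

`render_report()` refuses to emit an internally inconsistent report: the
expected net benefits must reproduce `mean QALY·λ − mean cost`, the base
case and summary must share a threshold, and the reported
cost-effectiveness probability must equal the CEAC at the threshold.

## Synthetic life table

Background mortality comes from a synthetic Gompertz–Makeham table
(`synthetic_life_table()`): annual hazard `a + b·e^{c·age}` with defaults
a = 5e-4, b = 3e-5, c = 0.09 over ages 0–100, giving adult mortality of a
plausible middle-income-country magnitude (qx ≈ 0.0016 at 40, ≈ 0.05 at
80, median death in the mid-80s). The terminal age is forced to qx = 1,
which is what guarantees finite lifetimes: with these defaults roughly 7%
of an age-18 cohort would otherwise still be alive at 100. It is a
deterministic stand-in for national period life tables, which are external
data; any real table can be supplied as CSV (`read_life_table()`), with
sex-specific rows blended by the cohort's female proportion
(`blend_life_table()` — the blend is applied to qx at each age, the
standard cohort simplification that does not track the survivors' sex
composition). The cohort starts at age 18 (the modelled population is
adults) with a combined-sex table; neither a starting-age distribution nor
a sex mix is published, so these scenario defaults are assumptions, not
inferences.

## Numerical choices

* 365.25-day year everywhere (discounting, rate conversions, life-table
  compounding), so conversions are mutually consistent.
* Lifetime horizon = run to the terminal life-table age or until the alive
  mass falls below 1e-9, whichever comes first (2,141 cycles from age 18
  with the default table).
* Occupancy conservation is maintained to 1e-12 per cycle; the engine is a
  closed-form cumulative-product recursion, verified against an
  individual-level microsimulation (50,000 subjects, agreement within 4
  binomial standard errors at every cycle).
* Adherence blending is computed as `reverted + (1-d)·(adherent -
  reverted)`, which returns a sub-trace exactly at d ∈ {0, 1} and blends
  identical sub-traces to themselves exactly (so a null treatment effect
  with zero drug cost yields increments of exactly zero).
* ICERs are always computed from full-precision internals, never from
  rounded summaries.

## Test scale

The shipped test suite exercises the full lifetime model: property tests
run on short horizons (40–200 cycles) for speed; the engine/oracle
equivalence uses 50,000 simulated subjects on 100–120-cycle horizons; the
probabilistic analysis in the end-to-end suite and the acceptance script
uses 10,000 lifetime draws.

## What the defaults imply (and limitations)

With the packaged inputs, add-on tiotropium buys QALYs but is **not**
cost-saving: the drug costs ≈ US$926/year while on treatment, whereas the
avoidable exacerbation cost is at most 1.14 events/year × 28% reduction ×
mean episode cost (≈ US$1,000 under the default severity split) ≈
US$320/year. No severity split of the 1.14 rate can close that gap, so
the base case lands in the north-east quadrant (ICER ≈ US$55,000/QALY,
above the US$5,180 threshold) and the incremental NMB stays negative
across the one-way DSA ranges. A cost-saving conclusion requires higher
event rates (the underlying cost-of-illness source reports 1.4 ED visits
and 2.5 hospitalizations per person-year, inconsistent with the 1.14
total) or markedly higher per-episode costs; users can supply such inputs
via `load_parameter_set()` overrides.

Other limitations: indirect costs are not modelled separately (the cost
inputs are taken as already societal); there are no post-exacerbation
tunnel states and no age- or sex-specific utility norms; the
microsimulation is a verification oracle, not a production engine; and
the synthetic life table emulates only the broad age-shape of real
mortality, not period effects, so passing tests demonstrate internal
correctness of the model mechanics rather than calibration to any
particular population.
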