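---
title: "Model and methods: cost-effectiveness of community CRC screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: cost-effectiveness of community CRC screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crcscreen)
```

## The question and the comparison design

A one-off community screening round (free stool test and risk
questionnaire, colonoscopy for positives) produces a cohort of diagnosed
and immediately treated residents: mostly adenomas removed during
colonoscopy, some advanced adenomas, and early-stage colorectal cancers
(CRC) treated with radical surgery. The economic question is what that
detection was worth. The comparison design follows the published
evaluation of the 2014–2016 Shanghai community programme this package
re-implements as a tested pipeline: the same diagnosed cohort is run
twice through a Markov model, once starting from its treated states
(screening arm) and once from the untreated states it would have
occupied had it never been screened (no-screening arm). The screening
round changes only the initial distribution, never the natural-history
transition probabilities — a deliberately conservative reading in which
screening buys earlier treatment, not a different disease.

Costs take the payer perspective (programme plus direct medical costs,
USD, converted at 6.3743 RMB/USD). Effects are life years (LY) and
quality-adjusted life years (QALY); both are discounted at 3%/year
(`model$discount_rate_costs`, `model$discount_rate_effects`).

## States and transitions

Fifteen conceptual states: normal, adenoma (< 10 mm), advanced adenoma
(≥ 10 mm), two 5-year post-polypectomy surveillance states, undiagnosed
CRC I–IV, post-treatment CRC follow-up I–IV, death from CRC, death from
other causes. The surveillance states are *tunnels*: a member spends
`model$tunnel_years` (default 5) consecutive cycles under surveillance
and then returns to normal, which `expand_state_space()` encodes as
year-indexed sub-states (23 computable states in the base case).

Annual transition probabilities are the base-case values of the
published evaluation (adenoma → advanced adenoma 0.020, advanced
adenoma → undiagnosed CRC I 0.0326, stage progression 0.24/0.36/0.175,
symptomatic diagnosis 0.20/0.20/0.65/1.00). Stage-specific annual CRC
mortality comes from registered 5-year survival via
`survival_to_mortality()`: $S_a = S_5^{1/5}$, $M = 1 - S_a$, giving
0.0218/0.0458/0.0994/0.2028 for stages I–IV.

### Mortality structure

Each living state carries a single dominant death risk:

* normal, adenoma, advanced adenoma and the surveillance tunnels die
  only from other causes, at the crude rate 0.0175/year;
* CRC follow-up states die only from CRC, at the stage-specific annual
  mortality;
* undiagnosed CRC states carry no death risk of their own — symptomatic
  diagnosis is their only exit (undiagnosed stage IV is diagnosed with
  certainty each cycle).

This structure was identified from the published 25-year death tallies,
which it reproduces essentially exactly (e.g. screening-arm CRC deaths
equal the initial stage counts times $1 - S_a^{25}$, and other-cause
deaths equal the non-CRC mass times $1 - 0.9825^{25}$). The obvious
alternative — layering the crude rate multiplicatively on every alive
state — shifts all death counts by 10–20% away from the published
values and was rejected. The cost of this fidelity is a mild
inconsistency: CRC patients are exempt from background mortality, so
their survival is slightly optimistic; with a 25-year horizon and the
dominant CRC hazards, the effect on incremental results is small.

### Re-progression after surveillance

`model$post_treatment_progression` (default `FALSE`) controls whether
members who return to normal after surveillance can re-enter the
adenoma–carcinoma sequence. Two observations force the default off:
the published one-way sensitivity analysis shows the ICER exactly
unchanged when the normal → adenoma probability moves ±25% (only
possible if that transition is inert), and the published screening-arm
totals match the no-re-progression run to within rounding. With the
switch on, re-progressed members incur the ordinary symptomatic
diagnosis costs; there is no repeat screening.

## Rewards, discounting, half-cycle correction

State-membership rewards use weights
$w_t = (1+r)^{-t}$ for $t = 0,\dots,25$ with **half weight at the first
and final cycle** — the classic half-cycle correction, crediting members
who transition mid-cycle with half a cycle on average. The trapezoid
variant (averaging adjacent occupancies inside the discount sum) is
algebraically close but sits a uniform $\sqrt{1+r} \approx 1.5\%$ lower
than the published LY totals, whereas the end-point weighting reproduces
them to 0.003%; the end-point form is therefore the implementation.
With `half_cycle_correction = FALSE` the weights are simply
$(1+r)^{-t}$ over cycles $1..25$, which makes undiscounted life years
equal the raw occupancy sum — a property the tests assert exactly.

One-time costs are not half-cycle corrected: the screening arm pays the
programme allocation (USD 1,271.90 per diagnosed resident: 280.83
initial-screening share + 158.73 per colonoscopy × 82,729/13,250) and
the initial treatment costs at cycle 0 undiscounted; both arms pay the
stage treatment cost on every flow into a CRC follow-up state,
discounted at the cycle of the flow. Death counts are horizon occupancy
times cohort size, reported as whole persons.

## Utilities

Table utilities: normal 1.000, adenoma 0.871, advanced adenoma 0.827,
CRC I–IV 0.829/0.860/0.814/0.738. Three assignments are genuinely open
and are exposed in `utilities`:

* the two surveillance tunnels default to their source-lesion utility
  (0.871/0.827) — post-polypectomy surveillance is not full health;
* undiagnosed CRC defaults to full health
  (`undiagnosed_full_health = TRUE`): these cancers are by construction
  asymptomatic until diagnosis. This choice reproduces the published
  no-screening QALY total to 0.1%, whereas stage utilities in the
  undiagnosed states fit visibly worse;
* CRC follow-up states carry their stage utility indefinitely.

A caveat the tests document honestly: under *no* assignment consistent
with the trajectories that reproduce the published LYs and deaths does
the published screening-arm QALY total (and hence the published
incremental QALYs and cost-per-QALY) emerge; the implied mean utility
of the surveillance tunnels would have to be ≈ 0.79, below every
published value. The package reports what its stated conventions
compute (incremental QALYs ≈ 17,465 rather than ≈ 13,984), and the
corresponding acceptance checks are expected to sit outside their
tolerance. The undiscounted-scenario ICER is similarly hypersensitive
(its numerator is a small difference of large cost totals; a 1% change
in the no-screening cost total moves it 10%) and lands ≈ 9% below the
published figure while all 3%-discount quantities agree within 1.5%.

## The synthetic registry

`generate_registry()` emulates the data the estimation stage would see:
a cascade (screen → positive → colonoscopy → diagnosis → category) with
the published rates as defaults (positivity 284,287/1,097,656,
colonoscopy uptake 82,729/284,287, diagnosis 13,250/82,729, category
mix from the six published counts); per-patient hospitalisation costs
from a log-normal law whose median is the configured median (log-scale
SD 0.6, a typical inpatient-cost skew) contaminated with a 2% fraction
of gross (10–30×) outliers so the outlier rule has work to do; and
five years of per-patient follow-up with stage-specific cancer death
competing with crude other-cause death. Quota mode fixes cascade counts
at their expected values, reproducing the published totals exactly at
full scale. The generator is deliberately simple: no ages, sexes or
districts (the model uses none), no false-negative progression, no
repeat rounds. Passing recovery tests therefore show the estimators are
consistent for this data-generating law — not that real registry data
meet its assumptions (independent cascade steps, log-normal costs,
constant hazards).

`estimate_from_registry()` inverts the generator: diagnosis-count
fractions (`initial_distribution()`, exact before 4-decimal half-up
reporting), the per-diagnosed cost allocation (`per_capita_cost()`,
2-decimal half-up), outlier-cleaned cost medians, and cause-specific
5-year survival by discrete product-limit with other-cause deaths
censored, annualised through `survival_to_mortality()`.

## Numerical choices and degenerate inputs

* Transition-matrix rows must sum to 1 within 1e-12 (constructed, then
  asserted); occupancy conservation is asserted at 1e-9.
* Initial fractions must sum to 1 within 5e-4, accommodating 4-decimal
  rounding of registry-derived fractions.
* Outlier rule: Tukey fences ($Q_1 - 1.5\,\mathrm{IQR}$,
  $Q_3 + 1.5\,\mathrm{IQR}$) on log costs. Median-centred fences were
  considered and rejected: on small skewed samples they clip legitimate
  low-cost observations.
* Money is rounded half away from zero at report time only; internal
  arithmetic is unrounded, and ICERs are computed from unrounded deltas
  (the published ICER cannot be recovered from the rounded table
  inputs).
* A zero-cycle horizon accrues no person-time and only upfront costs;
  an all-dead cohort accrues nothing; a zero incremental effect yields a
  dominance flag, never a division. Cheaper-and-better /
  costlier-and-worse quadrants are flagged dominant/dominated instead of
  reporting signed ICERs.
* The discount sweep moves both rates together; the colonoscopy-cost
  sweep varies the 158.73 unit cost and recomputes the per-diagnosed
  allocation, leaving the initial-screening share fixed.

## Problem sizes in the test suite

The suite runs the full 13,250-member, 25-cycle model (deterministic and
fast). Stochastic checks use sizes chosen for tight-but-cheap
tolerances: 200,000-participant registries for cascade-rate recovery
(3 binomial SDs), a 60,000-row balanced-mix registry for cost-median
(2%) and survival recovery, and a count-level Monte-Carlo
microsimulation oracle (20 replicates × 50,000 individuals on a
short-horizon configuration, agreement within 3 Monte-Carlo SEs).

## Limitations

Beyond the published design's own exclusions (no screening-test
sensitivity/specificity, no colonoscopy complications, no repeat
rounds, no recurrence after surgery, no indirect costs, one crude
age-independent background mortality), the package inherits the
identified conventions above; users who prefer a fully multiplicative
mortality structure or different follow-up utilities can set them in
the configuration, at the price of drifting from the published totals.
Only one-way sensitivity analysis is provided — no probabilistic
sensitivity analysis — matching the scope of the evaluation it
re-implements.
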