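---
title: "A desk-scale microsimulation of cancer primary prevention"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A desk-scale microsimulation of cancer primary prevention}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oncoprev)
```

## What the model is

`oncoprev` is a dynamic microsimulation of cancer-related health and
economic outcomes under primary-prevention policy. It simulates explicit
individuals on an annual cycle: each person carries a birth year, sex and
migration status (the demographic layer), a permanently assigned quantile
for each of four behavioural risk factors — BMI, physical activity,
sedentary time and alcohol consumption (the risk-factor layer) — and a
disease history for four cancers with an established link to those factors:
breast, colorectal, oesophageal and liver cancer (the disease layer).
Policies are evaluated by differencing an intervention run against a
business-as-usual counterfactual run that shares every random number
stream, so that the difference isolates the policy effect (common random
numbers).

All inputs are synthetic and generated by the package itself: a stylised
country ("Synthetica") with a stable population pyramid, a fixed quantile
structure for each risk factor by age band and sex, baseline incidence and
five-year case fatality per cancer, per-case annual treatment costs, and an
alcohol price-elasticity table. No real-country fidelity is claimed
anywhere; the point of the generator is to give every downstream stage
inputs with the statistical structure the method assumes, so the whole
pipeline is testable without any external data.

## The disease mechanics

**From quantiles to incidence.** An individual's relative risk (RR) for a
cancer is the product over risk factors of the RR attached to their
effective quantile — the multiplicative combination conventional in burden
-of-disease work. The bottom quantile is the reference (RR exactly 1);
harmful exposures have RR non-decreasing in the quantile, physical activity
(protective) non-increasing. The annual incidence probability is

  hazard = baseline(age, sex) x RR / mean(RR),

with the mean taken over the current at-risk (cancer-free) population of
the same age band and sex. This normalisation calibrates the simulation so
that a business-as-usual run reproduces the baseline rates in expectation
while individual heterogeneity follows the RRs; it is recomputed every
year, but always over *unshifted* (pre-intervention) exposures. Normalising
over post-intervention RRs would pin total incidence to the baseline and
cancel every intervention by construction, so the baseline-exposure reading
is the only internally consistent one; under business-as-usual both
readings coincide.

**Fatality and remission.** Each incident case draws death-within-5-years
from a (cancer, age band, sex) case-fatality probability. Predicted deaths
draw a year of death from five weights w1..w5 (default 0.40, 0.25, 0.15,
0.12, 0.08) that are strictly decreasing — mortality is highest in the
first year after diagnosis and declines thereafter — and constant across
ages, mirroring the data limitation that five-year cancer mortality is not
broken down by age. A case alive five full years after diagnosis is
considered recovered: it stops accruing treatment costs and cancer
mortality and cannot recur (no second primaries of the same cancer), while
all other risks continue. An individual can hold several concurrent
cancers, which is what the multimorbidity cost term prices. Scheduled
cancer deaths compete with background mortality; if background death comes
first, the scheduled death lapses.

**Costs and DALYs.** Costs follow a per-case annual basis: the sum of the
active cancers' annual costs, times a last-year-of-life multiplier
(default 2.5) in the year of cancer death, times a multimorbidity factor
`1 + 0.2 x (k - 1)` for `k` concurrent active cancers. DALYs are years
lived with disability (active case-years times a per-cancer disability
weight) plus years of life lost (cancer deaths times the synthetic life
table's remaining expectancy at the age of death), undiscounted by default.

## The six policies

The intervention constructors encode the published input values verbatim:

| policy | target | exposure | individual effect |
|---|---|---|---|
| menu labelling | age > 5 | 12% | 1.05–1.31% BMI drop |
| food labelling | age > 5 | 15% | 0.40% BMI drop |
| mass media campaigns | age > 18 | 100% | +60% activity at 1 month, +30% at 1 year, 0% at 2 years |
| workplace sedentary programme | 18–65 | 2.31–6.95% × 50% enterprise uptake | −72.78 min sitting per 8-h workday |
| alcohol tax | all ages | 100% | +10% price via elasticities (−4 to −7% consumption) |
| minimum unit pricing | all ages | 100% | floor price via price distribution (−0.6 to −3.3%) |

Design choices where the published description leaves the mechanism open:

* **Effect over time.** Only the mass-media campaign is given a decay
  path; it is linearly interpolated between its three knots and held at
  the last knot's value beyond them. All other policies hold their full
  effect for the whole horizon, and their time-to-maximum-effect is taken
  as immediate. Inside the annual cycle, effects are evaluated at mid-year
  (t − 0.5), so the media campaign contributes its average path to the
  first two simulated years rather than being sampled only at integer
  times.
* **Ranged magnitudes.** The menu-labelling effect is drawn uniformly per
  exposed individual from 1.05–1.31% (configurable to the fixed midpoint);
  the workplace exposure range 2.31–6.95% is a configurable scalar
  defaulting to the midpoint 4.63%, additionally thinned by the 50%
  enterprise participation rate.
* **Sedentary time** is kept as its own risk factor with its own RR
  column, and the workplace effect shifts it directly at
  72.78 × workdays/7 minutes per day (5 workdays assumed). Routing it
  through an activity-equivalent conversion would introduce an
  unidentifiable constant.
* **Percentage effects are relative** to the individual's current exposure
  value ("0.40% lower BMI" multiplies BMI by 0.9960).
* **Alcohol effects** map each individual's drinker age band (18–29,
  30–49, 50+; under-18s fall into the youngest band) and drinking category
  (heavy at 40 g ethanol/day and above) to a beverage-share-weighted
  consumption change. Because the change is multiplicative, zero
  consumption stays zero — abstainers are unaffected without a special
  case. The published −4 to −7% and −0.6 to −3.3% ranges are read as the
  span across elasticity cells, and the default elasticities and price
  distribution are *calibrated* (not estimated) so every cell lands inside
  them.
* **Exposure membership** uses a persistent per-individual uniform drawn
  at entry, compared to the exposure fraction under the current-age
  eligibility filter: membership is stable over time, individuals age into
  and out of eligibility, and paired runs see identical memberships.

## How an intervention changes incidence

Each individual's continuous exposure is reconstructed uniformly within
their permanent quantile's bin of the current (age band, sex) cell; a
persistent uniform keeps the within-bin position fixed for life. An
intervention shifts the continuous value, and the RR lookup then uses the
quantile whose mean is nearest the shifted value. Small effects therefore
move only the fraction of exposed individuals who sit close to a bin
boundary — an intentionally conservative discretisation that mirrors the
fixed-quantile architecture. The number of quantiles defaults to 5
(quintiles) and is configurable; the published description does not state
the number used upstream, nor the reference quantile, so both are explicit
choices here.

## Randomness and pairing

Every stochastic block (births, migration, background mortality, incidence
per cancer, survival draws, entry attributes) reseeds R's generator from a
deterministic function of (master seed, calendar year, event code) and
draws one uniform *per table row*, indexing by row position — never over a
state-dependent subset. Newborn attributes are additionally keyed to the
mother's row, so the same mother bears the same child in both paired runs.
This is the synchronized-streams discipline of common-random-number
designs: if draws were made only over the currently alive (or currently
diagnosed) subset, a single diverging death would shift every later
individual's position and decorrelate the remainder of both runs, burying
small policy effects in divergence noise. As implemented, regeneration is
bit-identical for a fixed seed; a zero-effect intervention reproduces the
counterfactual bit for bit (the tests assert this identity); and every
individual keeps an identical event stream across paired runs no matter
what happens to anyone else, which is what makes cases-avoided estimates
usable at desk scale. Replicate seeds are derived
from the master seed, and summaries report the replicate mean with a
percentile-bootstrap interval of that mean (resampling replicate values),
whose width shrinks like 1/sqrt(replicates); a raw percentile band across
replicates would not.

## What the generator emulates — and what it does not

The generator reproduces the *structure* real inputs would have: a
plausible pyramid with Gompertz–Makeham background mortality (net of the
modelled cancer deaths, to avoid double counting), age-peaked fertility,
small net in-migration at working ages, age-increasing cancer incidence
with realistic sex ratios (male breast cancer is set to zero to keep the
RR table small — a documented simplification), case-fatality levels that
rank liver and oesophageal cancer far above breast and colorectal, and
price elasticities that are larger for spirits than beer and smaller for
heavy drinkers. It does **not** emulate: secular trends in risk factors or
treatment, cohort effects, correlation *between* risk factors within an
individual (each quantile is assigned independently), realistic abstention
(the zero-consumption point mass is capped at 18% in every age band so
quantile means stay strictly increasing and identifiable — real youth
abstention is far higher), screening, stage at diagnosis, or any
country-specific level. Passing tests therefore demonstrate that the
*mechanics* — calibration, pairing, costing, policy arithmetic — are
correct, not that the absolute case counts transfer to any real
population.

## Numerical choices and degenerate inputs

* Pyramid expansion uses largest-remainder rounding, so the population
  total equals the requested scale exactly.
* Hazards are clipped to [0, 1]; a zero baseline gives a zero hazard for
  any RR; a non-positive mean RR is an error.
* If two cancers schedule a death for the same individual in the same
  year, the death is attributed to the first cancer in the fixed order
  (breast, colorectal, oesophageal, liver).
* A minimum-unit-pricing floor below the entire price distribution binds
  nothing and yields zero change (not an error).
* Consumption and sedentary time are floored at zero after shifts.
* Costs in the year of death are accrued in full (with the terminal
  multiplier when the death is from cancer); emigrants stop accruing
  anything from the year they leave.

## Problem sizes used by the test suite

The packaged checks run at sizes chosen to make Monte-Carlo error small
relative to the tested tolerances while keeping a laptop-scale runtime:
the incidence-calibration property uses a business-as-usual run of 100,000
individuals over 2020–2049 (the realised case count per cancer must sit
within 3 standard errors of the baseline expectation); parameter-recovery
checks use 10,000 simulated cases; and the direction/ranking properties of
the six policies use 20 paired replicates of 20,000 individuals over
2020–2050, with the six interventions sharing each replicate's
counterfactual run. The weakest policies (food labelling, the workplace
programme) avoid only a handful of cases at this scale, which is exactly
the regime the common-random-number pairing is designed for.

## Known limitations

Annual time steps cannot represent sub-annual dynamics (the media
campaign's one-month knot only enters through mid-year averaging).
Intervention effects on risk factors other than the targeted one, and
interactions between risk factors, are not modelled. Implementation costs
of the policies are outside scope, as are labour-market effects, so
reported savings are gross healthcare savings. Lung and other cancers not
directly linked to the modelled risk factors are excluded. Remitted
individuals cannot be re-diagnosed with the same cancer, which slightly
understates late recurrences.
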