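---
title: "A system dynamics model of regional mental health services and suicide prevention planning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A system dynamics model of regional mental health services and suicide prevention planning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phnsim)
```

## What the package models

`phnsim` implements a stock-and-flow system dynamics model of a regional
mental health service catchment and the planning analyses that sit on top of
it. The question the analysis machinery answers is a policy one: when a
state commissions suicide prevention programmes through semi-independent
regional catchments, how much is lost by imposing one state-wide portfolio
of interventions instead of letting each region pick the portfolio that
suits its own population and service system?

The model has four interconnected sectors, integrated jointly with a
fixed-step explicit Euler scheme at `dt` = 1/8 week (0.875 days) over a
20-year horizon starting 1 January 2011, with scenario comparisons made on
the 10-year forecast window from 1 January 2021 to the start of 2031:

* **Population** — births, net migration and background mortality act on all
  living-person stocks; births enter the low-distress stock, migration and
  mortality act proportionally to stock occupancy.
* **Psychological distress** — a two-state core (low distress, Kessler-10
  10–15, versus moderate-to-very-high distress, Kessler-10 16–50) with
  constant per-capita onset and recovery rates. Recovery operates at the
  untreated rate for people who are distressed at home or waiting for care,
  at a faster rate for people receiving care, and at a *reduced* rate for
  people who have disengaged from services (see below).
* **Mental health services** — help-seeking moves distressed people into a
  primary-care (GP) queue (with a fraction going directly to online
  services); GP episode completions split by referral fractions into a
  specialist queue (psychiatrists and allied health pooled), community
  mental healthcare, psychiatric inpatient care, online care, or discharge.
  GP and specialist intake is throughput-limited
  (`min(queue / admission lag, capacity)`); community care is
  throughput-limited and inpatient care bed-limited, with blocked referrals
  returning to the untreated pool. Waiting time is `queue / capacity`
  (capped at 52 weeks), and patients disengage from queues at a saturating
  rate `d_max · w / (w + tolerance)` of the current waiting time `w`, plus a
  constant dissatisfaction rate out of in-care stocks. Disengaged patients
  re-seek care at a reduced rate. Service capacities are stocks growing
  continuously at per-service yearly rates ("business as usual" growth).
* **Suicidal behaviour** — each risk group (distressed untreated, waiting,
  or disengaged at one rate; in care at a lower, protective rate; recently
  discharged from inpatient care at an elevated rate) generates attempts at
  `rate × occupancy`. A fixed fraction of attempts is fatal (removing the
  person and incrementing cumulative suicides) and a fixed fraction leads to
  a self-harm hospitalisation (moving survivors into inpatient care).
  Inpatient discharge feeds a post-discharge stock with first-order mean
  residence of 13 weeks — the elevated-risk aftercare window that
  post-attempt care targets. Emergency department presentations accrue at a
  per-distressed-person rate; this rate also scales the *reach* of
  ED-delivered interventions.

Every person flow is mirrored into a co-integrated population tally, so the
living stocks sum to the demographically implied population to machine
precision at every step — the closure invariant the test suite asserts at
1e-6 relative tolerance.

### Why queued patients recover and disengaged patients recover slowly

The model needs a mechanism by which *generating demand can do harm*:
programmes that raise help-seeking are beneficial where the service system
has slack, and harmful where it is saturated. We model this through the
recovery pathway rather than through differential attempt rates: people
waiting in a queue still remit spontaneously at the untreated rate, but
people who disengage after a poor service experience (excessive waiting or
dissatisfaction with care) remit at a substantially reduced rate (default
multiplier 0.15) while attempting at the ordinary untreated rate. Flooding a
saturated queue therefore converts recoverable untreated distress into a
persistent, slowly-recovering disengaged pool, raising prevalence and
suicide mortality; the same campaign in a slack system moves people quickly
into protective, faster-recovering care. Capacity relief acts by shrinking
exactly this pool.

## Time conventions

Time is measured in weeks; one model year is 52 weeks. The integration grid
is dated from 1 January 2011, so 1 January 2021 is week 520 and the start of
2031 is week 1040. Calendar drift of about 1.25 days per civil year is
accepted. The default step of 1/8 week is the conventional choice for
weekly-rate models of this kind; a convergence test confirms first-order
behaviour (halving `dt` more than halves the integration error), and a
closed-form check confirms per-capita-scale exponential decay is tracked
within 0.5% over ten model years. Note that 0.5% closed-form agreement is a
property of *slow* (per-capita-scale) rates: a decay as fast as 0.1/week
accumulates tens of per cent of first-order Euler bias over 520 weeks at
this step, for any integrator of this order.

## Parameters

All rates are per week, capacities in persons/week (beds for inpatient
care), durations in weeks, capacity growth in fractions per model year.
Defaults describe a mid-size catchment: population 800 000, distress
prevalence 28%, distress episodes lasting about six months untreated and
half that in care, 2% of the distressed seeking care weekly, GP capacity at
0.4% of population per week, referral fractions (specialist 0.25, community
0.15, inpatient 0.05, online 0.10, discharge 0.45), attempt rates of
6e-4 /week untreated, 2.4e-4 in care, and 1.2e-2 post-discharge, 30% of
attempts hospitalised, 1.5% fatal. `?catchment_parameters` documents every
field; `validate_parameters()` enforces non-negativity, fraction ranges,
referral fractions summing to one, and the protectiveness of care.

These values are a reconstruction: they were chosen so that the synthetic
state's behaviour (baseline suicide rates, waiting times, and the pattern of
single-intervention effects described below) is realistic, and they are
deliberately exposed — every one can be overridden per catchment via
`catchment_parameters()` or the YAML config files.

## The intervention catalogue

Thirteen interventions are modelled, each as a small set of *direct* effects
on parameters — multiplicative, additive, or replacing — switched on at
2021-01-01 and phased in linearly over 13 weeks (one quarter; roll-out
dynamics are not otherwise modelled). All indirect consequences emerge from
the model structure, so combined portfolios are non-additive; the tests
assert observable synergy (for example, care coordination rescues part of
the harm an awareness campaign does in a congested catchment).

Magnitudes are *calibrated-to-figure defaults*: they were set so that
single-intervention percentage reductions on the synthetic state fall in
realistic, heterogeneous ranges — post-attempt care roughly uniform near
4–7%; safety planning 4–5% in metropolitan catchments but 8–10% where
emergency department presentation rates are high (its reach is modelled as
proportional to the ED presentation rate); care coordination ~5%; social
connectedness ~5–6%; awareness campaigns from +0.7% in slack catchments to
−6% in starved ones; psychiatrist/allied health capacity growth worth ~2% in
specialist-saturated cities and ~0 elsewhere. Three of the thirteen entries
(`gp_capacity`, `online_services`, `ed_aftercare_outreach`) are flagged
`reconstruction = TRUE`: the catalogue size is fixed at thirteen but only
ten programme identities are well established, so the remainder are
plausible placeholders, replaceable via `intervention()` without code
changes.

## Scenario analysis

A scenario result is the cumulative suicides over the forecast window under
a portfolio, compared with the business-as-usual baseline (no new
interventions, capacity growing at current rates). Because interventions
only act from the window opening, the pre-window trajectory is shared by all
scenarios; `catchment_snapshot()` runs it once and restarts the integrator
from the stored state, which is exact for a fixed-step explicit scheme. The
exhaustive search (`combination_search()`) evaluates all C(13,4) = 715 and
C(13,5) = 1287 portfolios in every catchment; the state optimum maximises
the summed reduction, per-catchment optima maximise each column, the
regional planning benefit is their (non-negative) difference, and the
suboptimality count is the number of portfolios doing strictly worse in a
catchment than the state optimum does there. Reductions are rounded to 1e-6
persons before comparisons so floating-point noise cannot reorder ties, and
ties resolve to the lexicographically earlier set; "strictly worse" uses
`<` on the rounded values.

## Calibration

Free parameters are fitted to yearly observed series (distress prevalence,
suicides, self-harm hospitalisations, ED presentations, service usage) by
minimising the mean absolute per cent error, all observation points weighted
equally. The optimiser is a Powell-type direction-set search written in the
package: cycle through a direction set line-minimising each direction with
Brent search, then replace the direction of largest gain with the cycle's
net displacement. Box bounds are enforced by the smooth sinusoidal
reparameterisation `x = lower + (upper − lower)(sin z + 1)/2`, so every
visited point is feasible and the line searches are unconstrained (each
coordinate's full range corresponds to one period, which the `[−π, π]`
search interval covers). Convergence is declared on relative objective
change below 1e-4 (default) within 200 cycles; exhausting the budget
returns the best point found, flagged, rather than erroring. Because no
real calibration series ship with the package, validation is by parameter
recovery on synthetic data: with noise-free series generated from known
parameters, three free parameters are recovered within 1% relative and the
final MAPE is below 0.5%; with 5% multiplicative lognormal noise, recovery
stays within 10%.

## Sensitivity analysis

Uncertainty in the assumed intervention effects is propagated by Latin
hypercube sampling: 100 draws from independent uniforms spanning ±20% of
each direct-effect magnitude of the portfolio under study (the `lhs` package
provides the stratified design; one draw falls in each of the 100
equal-probability strata of every parameter). The sampled parameters act
only from the intervention start date, so the baseline is computed once.
Summaries are the mean, the 25th–75th percentile (50%) interval and the
2.5th–97.5th percentile (95%) interval, with linear interpolation between
order statistics (`quantile` type 7). These intervals measure sensitivity
to effect assumptions and should not be read as confidence intervals. The
seed is a required input and is logged with every design.

## The synthetic state

No real catchment data ship with the package. `generate_state()` produces
ten synthetic catchments spanning a deliberately wide envelope modelled on a
populous Australian state commissioned through ten PHN-like regions:
populations log-spaced over 243 000–1.57 million; target mean yearly suicide
rates spanning 7.61–12.18 per 100 000 and rising with remoteness; four
metropolitan catchments (generous overall capacity, slack 1.2–1.5, but
demand-saturated specialist services, slack 0.32–0.42 with slow growth),
four regional, and two remote catchments (ED presentation multipliers
1.5–2.0, overall capacity slack 0.60–0.80, slow capacity growth). An inner
bisection jointly scales the three attempt rates until each catchment's
baseline mean yearly suicide rate over the first ten model years is within
10% (in practice 2%) of its target. Profile ranges are generator defaults
describing a plausible state, not estimates for any real jurisdiction.

The generator is the package's fixture factory: it writes the same YAML
configs and CSV series the rest of the package reads, and
`generate_observed_series()` produces calibration targets by running the
model under known parameters and applying multiplicative lognormal noise
(which keeps values positive, as MAPE requires). What passing tests on this
state demonstrate is *structural* fidelity — the qualitative mechanisms and
the arithmetic of the analyses — not predictive accuracy for any real
region: the synthetic state has no age or sex structure, no seasonality, no
socio-economic gradients beyond a scalar disadvantage score, and its
"observed" series are generated by the very model being fitted.

## Numerical choices and degenerate inputs

* Negative-stock protection: Euler updates clamp at zero with a warning; the
  default parameterisations never trigger it (tested).
* Zero-capacity services report the capped waiting time (52 weeks), not
  infinity.
* The compiled integrator (C++) exists purely for throughput (the
  exhaustive search runs ~20 000 decade-long simulations); the pure-R
  engine is the reference, and a test holds the two to 1e-10 relative
  agreement.
* Problem sizes used by the tests and the analysis scripts: 20-year runs at
  dt = 1/8 week (8 320 steps) for all scenario work; 10-year runs for
  rate-matching and calibration; 100-draw sensitivity designs (10-draw
  smoke tests in the faster checks). The full k = 4 and k = 5 searches over
  ten catchments complete in about a minute on one core.

## Known limitations

Catchments are independent — no migration of patients or resources between
them, and no resource coupling in the state-level sum. The distress sector
is two-state; episode-duration heterogeneity and relapse structure are
collapsed into exponential rates. The disengagement and reach functional
forms are single-parameter choices among many plausible shapes. Intervention
effects ramp linearly and persist indefinitely; no decay, no
cost-effectiveness weighting, no budget constraints. The headline
percentages produced on the synthetic state (a ~21% best-4 and ~24% best-5
state-level reduction of a ~8 000-suicide baseline) characterise the
synthetic study conditions, not any real state's prospects.
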