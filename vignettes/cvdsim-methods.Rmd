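---
title: "Methods: a population-level system-dynamics model of CVD outcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a population-level system-dynamics model of CVD outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`cvdsim` is a deterministic stock-and-flow simulator of cardiovascular disease
(CVD) events, CVD deaths and the population living with post-CVD disability,
for an adult national population followed in annual steps. This vignette is
the package's own account of the model: the compartments and flows, the event
engine and its calibration, the numerical conventions, the synthetic-data
world the tests run in, and the design decisions taken where the design was
genuinely open.

## The model

### Population bookkeeping

The universal container is a `cohort_grid`: persons by single year of age
(18 to 99, plus an absorbing 100+ class) and sex. Each simulated year applies,
in a fixed documented order, (1) deaths, (2) disease-state transitions inside
the sub-models, (3) net migration, (4) ageing with an age-18 entry cohort.
Rates are annual fractions (explicit Euler with dt = 1 year; all published
parameters are annual rates). A configuration switch (`modes$hazard`)
reinterprets rates as instantaneous hazards via `1 - exp(-r)` for robustness
checks. Births are `fecund women x fertility rate`; because the model covers
ages 18+ only, the fecund 15--49 band is approximated by women 18--49 times a
correction factor (default 1), and the default age-18 entry rule simply
replaces the age-18 cohort (an exogenous entrant series can be supplied
instead). Conservation — change in total population equals entrants plus net
migration minus deaths — holds to floating-point accuracy by construction and
is asserted at 1e-9 relative tolerance over 100-year runs.

### Risk-factor sub-models

Diabetes and hypertension share one *two-stage* structure: healthy →
pre-condition → established condition, with the pre- and established-stage
stocks each split into *managed* and *unmanaged*. Flows: incidence (healthy →
pre, unmanaged), regression (pre → healthy), progression (pre → disease),
treatment uptake (unmanaged → managed, applied to both stages by default),
and deaths. Managed stocks die at `mortality x (1 - 0.13)` (the treatment
mortality effect) and progress at either an explicit managed rate (diabetes:
0.0134 vs 0.0556 unmanaged) or the unmanaged rate times a management effect
(hypertension: 0.33). Smoking is a three-state model: never → current
(initiation 0.0082388), current → former (cessation 0.162), former → current
(relapse 0.1), with 18-year-olds entering as never-smokers.

All outflows in a step are computed from start-of-step stocks. An oversized
combined outflow (rates summing above 1) is an **error** by default rather
than a silent clamp (`modes$on_negative = "clamp"` scales a cell's outflows
down with a warning). The established-disease state is absorbing except for
death, managed patients do not revert (a dropout rate exists and defaults to
0), and pre-stage regression applies to managed and unmanaged alike (a scope
switch restricts it to managed only).

### The CVD event engine

Each year the at-risk population (total minus post-CVD survivors) is
partitioned into the eight comorbidity groups of {diabetes D, hypertension H,
smoking S}. Lacking comorbidity data, the default partition assumes
independence of the three marginal prevalences (share(DHS) = p_D p_H p_S and
so on); an `even_split` mode seeds each factor's population evenly across its
four containing groups and reconciles to the marginals by iterative
proportional fitting. The annual event probability of group g at age a is
logistic:

p(g, a, sex) = 1 / (1 + exp(-(b0[g] + b_age[sex] a + b_D 1{D in g} +
b_H 1{H in g} + b_S 1{S in g})))

with published sex-specific slopes and per-group intercepts obtained by
calibration (below). Treatment adjusts the probability: the treated fraction
(coverage) of a group experiences risk multiplied by a factor derived from
the published relative risks (RR: diabetes 0.8, hypertension 0.5, smoking
cessation 0.5); for multi-factor groups the multipliers compose
multiplicatively under an independence assumption on management status.
Smoking "treatment" is cessation: by default, smoking-containing groups hold
ever-smokers and the coverage is the former-smoker share
(`modes$smoking_definition = "current"` instead removes quitters from the
groups entirely).

Events produce deaths at the event fatality rate (0.2); survivors accumulate
in the post-CVD stock, which is subject to background mortality times a
relative risk of 1.6, reduced by the treatment mortality effect (0.13) times
the fraction of post-CVD patients treated (1). Events remove people from the
at-risk pool for the year (no recurrent events). The age-adjusted incidence
rate is computed by direct standardization, with the model's own initial
(2010) at-risk population as the default standard.

### The adjustment-mode decision (`modes$eq10_literal`)

Treatment-effect parameters labelled "relative risk" admit two readings, and
the choice inverts the model's headline result. Read as a risk *multiplier*
(treated risk = RR x p, so RR_d = 0.8 means a 20% reduction), the
hypertension intervention would dominate the diabetes one: the two
interventions act on near-equal event shares with similar coverage deltas,
and hypertension's 50% effect would outweigh diabetes' 20%. Read as the
*complement* of the multiplier (treated risk = (1 - RR) x p, the form in
which this model family's adjustment equation is conventionally printed),
diabetes management has the largest population impact — the ordering this
model is known for, driven by the much larger diabetes logistic coefficient.
The package defaults to the second reading (`eq10_literal = TRUE`) because
it is the only one consistent with the model's reference results, and keeps
the first as `eq10_literal = FALSE`. Both modes are exercised in the test
suite; the exported `adjusted_probability(p, coverage, rr)` always
implements "treated risk = rr x p", with the mode controlling only how the
configured RRs are translated into that multiplier.

### Parallel sub-models and the ledger

The three risk-factor sub-models each partition the whole population, but
their death flows differ slightly (managed-mortality effects) and CVD deaths
are not native to any of them, so their totals would drift apart from the
demographic ledger over decades. The package keeps a single ledger population
— the one on which conservation is enforced exactly — and, by default
(`modes$renormalize`), rescales each sub-model's stocks cell-wise to the
ledger at the end of every year. Prevalence ratios are unchanged by the
rescale; what is assumed away is any covariance between risk-factor state and
CVD/managed-mortality excess within an age-sex cell.

## Calibration

**Intercepts.** Given a total annual event count and an expert distribution
of events over the eight groups (none 1%, D 20%, H 10%, S 5%, DH 29%, DS 5%,
HS 15%, DHS 15% — summing to 100%), each group's intercept solves the
monotone one-dimensional equation "expected events = target events" by
safeguarded Newton iteration to an event mismatch below 1e-10 (bisection
fallback; `uniroot` as last resort). The expected-event formula uses the
*unadjusted* logistic, matching the calibration contract; simulated events
under prevailing treatment coverage are therefore somewhat below the anchor.
A zero target with positive population yields `-Inf` (flagged); a target at
or above the group population is an error. Round-trip recovery of generating
intercepts is exact to 1e-8 by construction and asserted in the tests.

**Rates.** `fit_rates()` fits any named subset of configuration parameters
(typically the calibration-sourced incidence/initiation/uptake rates, or a
migration multiplier) by minimizing the sum of squared relative errors
between simulated and observed aggregate prevalence and event series, with
L-BFGS-B inside box bounds, parameter scaling set to the starting values, and
a deterministic start from the configuration. Relative loss was chosen
because the series span orders of magnitude (prevalences near 0.1, events in
the tens of thousands); absolute loss is available. Non-convergence is
returned as a flag and warning, never silently. On noise-free self-generated
targets the generating rates are recovered well within 1%; with 2%
multiplicative lognormal noise over 30 annual observations, within 5%
(both asserted).

## Scenarios and sensitivity

Scenarios are timed step overrides of configuration parameters, held constant
once effective: diabetes uptake 0.05 → 0.15 in 2020; hypertension uptake
0.035 → 0.135; smoking cessation 0.162 → 0.25; and the combination of all
three. Comparison reports `100 x (base - scenario)/base` at a stated year and
within-scenario percent change over the horizon. The sensitivity experiment
draws the three calibrated rates (diabetes incidence, hypertension incidence,
smoking initiation) independently and uniformly from ±50% of baseline — the
stated variation was "two-way" with no distribution given, so joint
independent uniform draws are the default, with one-at-a-time and pairwise
grid modes available — runs 500 trajectories (seeded, bit-reproducible), and
summarizes each outcome-year by the mean and the empirical 2.5th/97.5th
percentiles ("minimum and maximum values at 95% confidence level" is read as
an empirical percentile interval).

## The synthetic world

Every external input is replaced by a generator with known ground truth:

* **Demography**: a parametric age pyramid (Gaussian bump centred at 42
  years, spread 18, floor 0.35 — a stylized mature-population profile),
  Gompertz mortality `m(a) = k e^{0.085 a}` with k = 5e-5 (female) and 8e-5
  (male) (≈0.5% at 60 and 4.5% at 80 for women — realistic adult life-table
  curvature), constant fertility 0.033 births per fecund woman per year
  (roughly a total fertility rate of 1.15 spread over 35 fecund years), zero
  net migration, and replacement age-18 entry.
* **The packaged fixture** anchors its 2010 aggregates to the published
  initialization values: 369,133 diabetics, 659,958 hypertensives, 414,789
  current smokers, 112,606 CVD survivors, 33,292 CVD events; total adult
  population 3,190,685 (chosen so current smokers are exactly 13%). Initial
  managed shares are 44% (diabetes) and 43% (hypertension), applied to both
  pre- and established stages. Values not published anywhere were fixed once
  at field-plausible levels: pre-diabetes prevalence 14%, prehypertension
  30%, former smokers 10%, all age-flat; established-condition and post-CVD
  prevalences follow logistic-in-age shapes (midpoints 50/52/70). All counts
  scale linearly with the `scale` argument, and intercepts are re-calibrated
  to the fixture.
* **Observations** for parameter-recovery tests are produced by running the
  model under true parameters and applying seeded multiplicative lognormal
  noise.

What a green test does *not* establish: the synthetic world is demographically
near-stationary (no migration, replacement entry), so its base-case event
*level* declines slowly as treatment coverage drifts up, unlike the published
projection in which a growing, ageing population drives events up 160% by
2040. Reproduction of the published quantitative table would require the
actual national demographic and registry series and re-calibration to them;
the package's desk-scale claims are the structural properties (conservation,
engine equivalence, calibration round-trips, parameter recovery) and the
qualitative scenario ordering (combined < diabetes-only < base; diabetes >
hypertension > smoking in 2040 event reduction), which the fixture reproduces.

## Numerical conventions and edge cases

* Tolerances: conservation 1e-9 relative; intercept calibration 1e-10 on the
  event mismatch; vectorized engine vs per-person summation 1e-12 relative.
* Empty cohorts: prevalence is `NA` per cell and excluded from aggregates;
  empty cells are excluded from age standardization with a warning; migration
  into an empty cell enters the sub-model's entry stock.
* Negative stocks: forbidden; inputs that would produce one (net
  out-migration beyond survivors, oversized outflows) error by default.
* Determinism: every stochastic element (sensitivity draws, observation
  noise) is governed by an explicit integer seed; identical seeds give
  bit-identical results.
* Configuration is validated structurally (unknown keys rejected, offending
  key named) and for bounds; JSON is the only config format (YAML support was
  dropped because no YAML parser is part of the package's guaranteed
  dependency environment).

## Known limitations

* Incidence, initiation and uptake rates are applied age-uniformly; the
  original model's (unpublished) age profiles may differ.
* The annual renormalization to the ledger assumes risk-factor state is
  independent of CVD-death and managed-mortality excess within a cell.
* No recurrent CVD events, no stroke/IHD subtypes, no costs.
* The fixture's demography is deliberately stylized; it is a test world, not
  a projection of any real population.

## A worked example

```{r, eval = FALSE}
library(cvdsim)
fx <- make_singapore_like_fixture(scale = 1)
base <- run_scenario(preset_scenario("base"), fx$inputs, fx$state, fx$config)
dia  <- run_scenario(preset_scenario("diabetes"), fx$inputs, fx$state, fx$config)
compare_scenarios(dia, base, year = 2040)
report_table(list(base = base, diabetes = dia))
```
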