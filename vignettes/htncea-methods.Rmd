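---
title: "Modelling the cost-effectiveness of hypertension treatment with htncea"
author: "htncea package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the cost-effectiveness of hypertension treatment with htncea}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(htncea)
```

# The problem

Hypertension is the leading treatable driver of cardiovascular disease in
sub-Saharan Africa, yet treatment coverage is low (the default book assumes
28.4% of diagnosed hypertensives are on medication) and blood-pressure
control among the treated is poor. A health ministry deciding whether to
fund guideline-based treatment — medication, monthly follow-up, monitoring,
and a national programme layer — needs to know what full implementation
costs from a societal perspective, and what it buys in averted death and
disability.

`htncea` answers this with a discrete-time Markov cohort model of an adult
(30+) hypertensive population under two scenarios: *treated* to the
International Society of Hypertension 2020 targets (BP < 130/80 mmHg below
age 65, < 140/90 mmHg at 65+) and an *untreated* natural-history null. The
effectiveness unit is the disability-adjusted life year (DALY); the summary
measures are the incremental and average cost-effectiveness ratios (ICER,
ACER), net monetary benefit (NMB), and GDP-multiple threshold labels, with
one-way deterministic and probabilistic sensitivity analysis on top.

# Model structure

## States and transitions

The state space (`htn_states()`) is:

* `untreated` — diagnosed but untreated hypertension (the null arm);
* `treated`, `controlled`, `uncontrolled` — the treated arm; the cohort is
  classified into controlled/uncontrolled by the control rate;
* five acute event tunnels — myocardial infarction (`event_mi`), unstable
  and stable angina (`event_ua`, `event_sa`), stroke (`event_stroke`), and
  transient ischaemic attack (`event_tia`). A tunnel is occupied for exactly
  one cycle, so one-off acute costs and weights attach exactly once;
* matching `post_*` chronic states, absorbing survivors of each event;
* a single absorbing `dead` state.

The model runs 80 one-year cycles. State membership is counted at cycle
start with no half-cycle correction: the source model is silent on the
correction, the convention is documented here, and at an annual cycle
length over 80 cycles the difference is second-order relative to parameter
uncertainty.

Annual event risks derive from 10-year first-event probabilities via
`annualize_risk()`: either a constant annual hazard
$p_1 = 1-(1-p_{10})^{1/10}$ or, as a scenario, ten linearly increasing
annual probabilities whose survival product reproduces the 10-year risk
exactly (slope found by root-solving to 1e-9). Disease-related and
background mortality combine multiplicatively on the survival scale
(`combine_mortality()`), and treatment multiplies event probabilities by a
relative risk, clipped at 1 (`apply_treatment_effect()`).

Two simplifications are deliberate. First, re-entry of normotensives into
the hypertensive pool is a parameter
(`epi.incidence_normotensive`) defaulting to zero: the source framework
asserts the flow but never quantifies it, and a documented zero is more
honest than an invented rate. Second, treated-but-uncontrolled patients
receive *no* event-risk reduction by default
(`model.rr_applies_to_uncontrolled = FALSE`); they still incur treatment
costs. A partial-effect variant is one flag away.

Heart failure is not a separate state: the acute/post-event structure
follows the five enumerated tunnel events, and heart-failure morbidity
enters through post-event weights and mortality multipliers.

## Burden accounting

DALYs follow the simplified GBD-2010 conventions: prevalence YLDs (person-
years in a state times its disability weight), no time discounting of
health outcomes by default, no age weights. Years of life lost per death
are the residual national life expectancy at the age of death,
$\max(LE_{sex} - age, 0)$, with the male/female life expectancies 66.7 and
70.4 years. Flooring at zero means deaths above life expectancy contribute
no YLL — a visible artifact in the oldest band, where averting a death can
*increase* the measured DALY burden because survivors keep accruing
prevalence YLD. A full age-specific residual life table can be configured
to soften this; the default keeps the published normative values.

Comorbidity uses the multiplicative independence model:
$P_{1+2} = 1-(1-P_1)(1-P_2)$, the same form for combined disability
weights, and for per-person YLD *rates*. The rate restriction is enforced:
the combination formula is meaningless on absolute year totals, so inputs
above 1 are rejected rather than silently combined. Pill-taking disutility
(0.049, CI 0.031–0.072) is folded *onto* treated-state weights with
`combine_dw()` rather than subtracted from health, which keeps every
weight inside [0,1].

## Costing

Costing is societal. Direct medical costs are bottom-up: annual medication
(placeholder 16 USD/year, built from dual low-dose therapy at the bundled
price-book pack prices, varied ±20% in sensitivity analysis), monitoring,
twelve outpatient visits at the WHO-CHOICE secondary-hospital fee (12 ×
0.49 USD), acute-episode costs per incident event (MI 1,040 USD, stroke
940 USD from the book; angina and TIA scaled placeholders), and annual
post-event outpatient care (45 USD coronary, 67 USD stroke). The national
programme layer costs 128.28 USD per treated person-year, the published
per-person figure after scaling the national cost by the 3% study-population
share. Direct non-medical costs add transport (42 ETB/visit) and patient
time valued at the employment-weighted daily wage (97.00 vs 26.53 ETB).

Indirect costs monetize lost productive years by the human-capital
approach. Each YLL/YLD year is valued at twelve months of the
employment-weighted wage mix — employment rates 0.88 (men) and 0.33
(women), employed monthly income 2,059.078 ETB (inflation-adjusted by
1.372 to 2021), unemployed monthly wage 796 ETB — and converted at 43.5
ETB/USD. Premature-mortality years per death are floored at zero above
life expectancy. All internal arithmetic is unrounded; rounding to two
decimals happens only in reporting.

Costs are discounted at 3% annually (6% as sensitivity). The source
description both adopts the GBD no-discounting convention for DALYs and
elsewhere discounts "costs and outcomes"; the package resolves this in
favour of undiscounted DALYs by default, with
`costs.discount_outcomes = TRUE` enabling outcome discounting for
sensitivity runs.

# Parameters

Everything lives in one validated book (`default_parameters()`,
overridable via `load_parameters()` with a named list, JSON, or long-format
CSV). Key entries, with defaults and why:

| parameter | default | basis |
|---|---|---|
| prevalence by band | 19.6 / 23 / 25.9 / 41.9 % | published survey bands |
| treatment coverage | 0.284 | national STEPS estimate |
| BP control on treatment | 0.70 | trial-achievable control; DSA range 0.50–0.70 |
| all-cause mortality RR, untreated | 1.39 (0.95–1.95) | published cohort meta-estimate |
| treatment RR, coronary events | 0.78 (0.70–0.87) | BP-lowering trial meta-analyses |
| treatment RR, stroke | 0.62 (0.53–0.72) | BP-lowering trial meta-analyses |
| disability weights | untreated 0.323, controlled 0.171, hypertensive heart disease 0.246 (0.201–0.300) | GBD weights |
| GDP per capita | 936.30 USD (2020) | threshold anchor; band 936.30–2,808.90, half-GDP 468.15 |
| willingness to pay | 50,000 USD/DALY | NMB reporting value |

Ten-year event risks by age/sex, background mortality, case fatalities
(MI 0.30, stroke 0.25, …) and post-event mortality multipliers are
*documented placeholders* in the Framingham/registry range: the study's
supplementary transition tables are not public, so these values define a
plausible stated world rather than reproduce the original one. They are
ordinary book entries and fully configurable. Consequently the package's
headline model outputs (ICER versus null, total deaths averted, the
"≥99.7% of draws cost-saving" PSA claim) are *not* reproductions of the
published headline numbers and are not asserted anywhere; with the default
book the deterministic run lands within the very-cost-effective band,
incurring cost (the programme layer dominates) while averting DALYs — a
qualitative, not numerical, echo of the original.

## Uncertainty

`uncertain(mean, low, high, family)` couples every uncertain quantity with
a 95% interval and a sampling family: beta for probabilities and weights,
gamma for costs, lognormal for relative risks, point for degenerate values
— the standard health-economics assignment, since the source reports only
intervals. `expand_uncertain()` pins the distribution mean to the point
estimate and chooses the one remaining shape parameter by percentile
matching (minimising squared 2.5/97.5 mismatch, `optimize` at tolerance
1e-8 on the parameter). With one free parameter and two targets the match
is exact only for self-consistent intervals; a residual above half the
interval width is treated as an infeasible mean/CI combination and
rejected. Tests verify fits by re-simulation at n = 1e5: means within 3
standard errors, percentiles within 2%.

# Sensitivity analysis

`one_way_dsa()` re-runs the pipeline at a parameter's bounds with
everything else at base case; a zero-width range reproduces the base case
exactly. `apply_scenario()` implements the named scenario transforms:
adherence multiplies the *achieved risk reduction*
($rr_{eff} = 1 - a(1-rr)$, so 50%-lower adherence on rr 0.7 gives 0.85), a
treatment lag suspends the reduction for its first cycles, pill disutility
folds into treated-state weights, and the linear-risk switch changes the
annualisation profile.

`run_psa()` samples the included uncertain parameters independently
(correlations are unreported in the source, so none are imposed), re-runs
the pipeline per draw, and reports empirical 95% uncertainty intervals
(linear interpolation between order statistics, `quantile` type 7 — the
interpolation rule is a documented choice), quadrant fractions on the
cost-effectiveness plane, and the cost-saving fraction. The seed is always
explicit; 20200901 (the study start month) is the documented default, with
no hidden entropy. Point-mass books reproduce the deterministic run
bit-for-bit, which is tested. `ceac()` converts the draw cloud into the
acceptability curve: the fraction of draws with positive NMB at each
willingness-to-pay value; at zero WTP this is the cost-saving fraction and
for large WTP it converges to the fraction of draws averting DALYs.

# Synthetic data

The generators exist so that the entire pipeline — including the costing
surface — can be exercised with no external data.

* `sample_size()` implements the single-population-proportion formula. The
  published chain is deliberately reproduced step for step: the base size
  is rounded to the nearest integer (1.96² × 0.14 × 0.86 / 0.05² = 185.01
  → 185), the 10% non-response inflation is kept fractional (203.5), the
  design effect of 2 doubles it, and only the final value is rounded up
  (407). The alternative reading of the anticipated proportion as the
  28.4% treatment rate appears in the same source passage; 14% is the
  default because it reproduces the printed chain.
* `generate_population()` draws a stratified cohort with treatment and
  control status at the book's rates; expected proportions match the
  specification and everything is reproducible from the seed.
* `generate_patient_records()` emulates the facility cost survey: 407
  patients allocated exactly 212/107/88 across three hospitals, each with
  a sampled regimen, Poisson visit/lab/bed-day counts, and every ledger
  line priced from the unit-price book. The goal is structural realism
  for testing the costing surface — the visit and comorbidity intensities
  are simple documented defaults, not epidemiological estimates.
* `generate_psa_fixture()` materialises parameter draw tables.

A green test on synthetic data establishes that the arithmetic, the
invariants and the plumbing are right; it cannot establish that the
placeholder risk schedules match Ethiopian epidemiology.

# Numerical choices and degenerate inputs

* Transition-matrix rows must sum to 1 within 1e-9; residual mass stays in
  the current state, and a row whose event-plus-death mass exceeds 1 is an
  error naming the state rather than a silent renormalisation.
* Cohort mass conservation is enforced at 1e-6 over 80 cycles; the engine
  is cross-checked against an exhaustive path-enumeration oracle at 1e-12
  on small chains.
* The sample-size ceiling subtracts 1e-9 before rounding up to absorb
  floating-point creep (185 × 1.1 × 2 is 407 + 1e-13 in doubles).
* Zero-width uncertainty intervals short-circuit to point masses before
  any fitting; beta fitting requires a mean strictly inside (0,1).
* ICERs with zero DALY difference raise an undefined-ratio error;
  negative ICERs are refused a threshold label (the dominance flag is the
  correct report). Threshold boundaries follow the published wording:
  exactly 1× GDP per capita is *cost-effective* (the band is "one to
  three"), as is exactly 3×; the half-GDP rule is inclusive at the
  boundary.
* Incremental results are stored in both orientations. The published
  tables print comparator-minus-intervention deltas (positive when
  treatment saves), and their ICER column is the quotient of those cells;
  `incremental()`/`icer()` reproduce that convention exactly. The fitted
  model's headline ICER uses the conventional incurred-cost-per-DALY-
  averted orientation unless the intervention is dominant, in which case
  the savings-per-DALY ratio is reported with the dominance flag.
  Dominance itself is symmetric: dominant means saving cost *and*
  averting DALYs, dominated means the reverse; cheaper-but-worse is a
  trade-off, not dominance.

# Worked example

```{r example, eval = FALSE}
fit <- htn_cea()
summary(fit)
psa <- simulate(fit, nsim = 1000, seed = 20200901)
plot(psa, type = "ceac")
```

# Known limitations

* The age-specific risk schedules are placeholders; absolute model outputs
  characterise the stated world, not the original study population.
* Strata age along calendar cycles but keep their band's risk schedule in
  bands, so risk rises in steps rather than continuously.
* The residual-life-expectancy floor under-counts YLL at old ages (see
  above).
* No treatment-resistant hypertension, no individual-level
  microsimulation, no EVPI, and no equity weighting — all outside the
  modelled scope.
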