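# htncea

Societal-perspective cost-effectiveness analysis of guideline-based
hypertension treatment in a low-income setting, built as a Markov cohort
model with DALY outcomes.

## What it does

Low treatment coverage and poor blood-pressure control make hypertension a
leading, largely preventable source of cardiovascular death and disability
in sub-Saharan Africa. `htncea` models an adult hypertensive cohort under
two arms — treated to the ISH 2020 blood-pressure targets versus an
untreated natural-history null — and asks what treatment costs society and
what it buys in averted burden.

The core is a discrete-time state-transition model run for 80 annual
cycles over states

```
untreated | treated -> controlled / uncontrolled
          -> event_{MI, UA, SA, stroke, TIA}  (one-cycle tunnels)
          -> post_{MI, UA, SA, stroke, TIA}
          -> dead  (absorbing)
```

with annual event risks derived from 10-year probabilities
(p₁ = 1 − (1 − p₁₀)^{1/10}, or a linearly increasing profile), background
and disease mortality combined multiplicatively on the survival scale, and
treatment acting through relative risks on coronary (RR 0.78) and
cerebrovascular (RR 0.62) events in the controlled fraction.

Outcomes are DALYs under GBD-2010 conventions — prevalence YLD
(person-years × disability weight), YLL = deaths × residual life
expectancy, multiplicative comorbidity adjustment
DW₁₊₂ = 1 − (1 − DW₁)(1 − DW₂). Costs are societal: bottom-up direct
medical costs from a bundled unit-price book, direct non-medical costs
(transport, patient time), programme costs, and human-capital productivity
losses valuing each lost year at twelve months of the employment-weighted
wage mix, converted at 43.5 ETB/USD and discounted at 3%. Results are
summarised as ICER/ACER (USD per DALY averted), net monetary benefit, and
WHO GDP-multiple threshold labels (very cost-effective < 1× GDP per capita
= 936.30 USD; cost-effective up to 3×; half-GDP interim rule), with
one-way deterministic and 1000-draw probabilistic sensitivity analysis and
cost-effectiveness acceptability curves.

Synthetic-data generators (stratified cohorts, a 407-patient
facility-allocated cost survey, PSA draw tables, the sample-size
calculator) let the entire pipeline run with no external data.

## Worked example

```r
library(htncea)

fit <- htn_cea()          # default parameter book: 100,000 adults, 80 cycles
fit
#> Hypertension treatment cost-effectiveness (Markov cohort model)
#>   cohort: 1e+05 persons, 80 cycles
#>   incremental cost (untreated - treated): -208064325.96 USD
#>   DALYs averted: 267460.95
#>   ICER: 777.92 USD per DALY averted
#>   threshold class: very cost effective
```

Treating the cohort costs more than not treating it (the negative
comparator-minus-intervention delta: medication, follow-up and programme
costs exceed the averted event-care and productivity losses) but averts
about 267,000 DALYs; the resulting 778 USD per DALY averted sits below the
one-GDP-per-capita line, i.e. very cost-effective. Age-band detail,
dominance flags, ACER and NMB come from `summary(fit)`.

Uncertainty:

```r
psa <- simulate(fit, nsim = 1000, seed = 20200901)  # probabilistic SA
psa                      # 95% uncertainty intervals, quadrant fractions
plot(psa, "ceac")        # acceptability curve over willingness-to-pay
one_way_dsa(fit$params, "costs.discount_rate", 0.03, 0.06)
```

Parameters live in one validated book and are overridable by dotted key:

```r
p <- load_parameters(list("epi.control_rate" = 0.5,
                          "costs.discount_rate" = 0.06))
htn_cea(p)
```

Note: the age-specific event-risk and mortality schedules in the default
book are documented placeholders (the original study's supplementary
tables are not public), so absolute model outputs describe the package's
stated world; the desk-checkable arithmetic — monetization formulas,
conversions, ratio and threshold logic, the sample-size chain — reproduces
the published figures exactly and is what the test suite asserts.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes, from the installed package, the published productivity-loss
monetizations (male and female years of life lost, female years lived with
disability, in ETB via the human-capital wage-mix formula) and writes them
as JSON; it also runs the full deterministic model plus a short seeded PSA
and reports the headline ICER to the console.
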