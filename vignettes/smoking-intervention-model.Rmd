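---
title: "A dynamic multi-state model of tobacco control scenarios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A dynamic multi-state model of tobacco control scenarios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`smokesim` implements a Markov-type, multi-state compartmental population
model for health impact assessment (HIA) of tobacco control policy. The
population is stratified by single year of age (0 to `age_max`, default 105),
sex, and smoking state: never smoker, current smoker, and former smoker by
whole years since quitting ("time-since-quit" classes `former_0`, `former_1`,
..., the last one open-ended). The causal chain runs from risk-factor
exposure to health: smoking class determines disease incidence through
class-specific relative risks (RRs), disease prevalence determines
disease-attributable mortality through per-disease excess mortality, and the
effect of smoking on deaths from causes outside the model is captured through
the relative risk on all-cause mortality.

Each projection year applies, in this order:

1. **Smoking transitions.** Never smokers start with probability `start(a,s)`;
   current smokers quit into `former_0` with probability `quit(a,s)`; former
   smokers restart with probability `restart(a,s)`, otherwise they advance one
   time-since-quit class (the top class is absorbing). People who change class
   carry their disease prevalence with them.
2. **Disease incidence.** Within each class, the disease-free fraction
   acquires each disease at the calibrated class-specific incidence.
3. **Mortality.** Each cell dies at its class-specific other-cause rate plus
   the prevalence-weighted excess mortality of its diseases.
4. **Ageing.** Everyone ages one year; newborns enter at age 0 as disease-free
   never smokers; survivors of the top age leave the model (the population is
   closed at `age_max`).

The ordering within a year is not dictated by the underlying theory and
changes results at second order in the rates; it is fixed as above and the
microsimulation oracle uses the identical ordering, so the two engines are
comparable step for step.

### Calibration of class-specific rates

Registries report *population-average* incidence `I_pop(a,s)`. With class
shares `w_c` and incidence RRs `rr_c` (with `rr_never = 1`), the never-smoker
incidence is `I_never = I_pop / sum(w_c rr_c)` and `I_c = rr_c I_never`, so
the share-weighted mean reproduces `I_pop` exactly. All-cause mortality is
split the same way using the all-cause RRs, and each class's other-cause
mortality is its class total minus its disease-attributable part (additive
mortality). Two contracts are enforced and tested: the share-weighted class
rates reproduce the observed population rates exactly, and the ratio of class
rates equals the input RR.

Two modelling choices here deserve emphasis:

* **Calibration uses the reference exposure distribution**, even when running
  an intervention. A price shock that moves smokers into the former classes at
  year 0 must not re-calibrate `I_never` upward, or the scenario would partly
  cancel its own effect. The underlying class-specific rates are properties of
  the population's epidemiology, estimated once from business-as-usual data.
* **Baseline disease prevalence is assigned uniformly across smoking
  classes**, because the input bundle stores only population-average baseline
  prevalence. Class differences in prevalence then build up dynamically
  through RR-scaled incidence. A bundle with class-specific baseline
  prevalence would sharpen early-year mortality differences slightly; the
  scenario *differences* reported by the package are affected much less, since
  both arms share the baseline.

### Net adolescent initiation rates

Adolescent surveys distinguish only smokers from non-smokers, so gross start
and quit flows cannot be separated below the adult-data age. The model uses
*net* initiation rates instead: the non-smoker prevalence curve is read as a
life table of a cohort that shrinks only through uptake, giving
`s(a) = (p_ns(a) - p_ns(a+1)) / p_ns(a)`. Quit and restart rates are held at 0
below the hand-off age (default 16). Noisy, locally increasing curves would
imply negative net rates; these are clamped to 0 with a warning, since the
cohort model admits no backward flow. The same algebra, applied to a *target*
curve, yields the start rates that hold a post-intervention adolescent
prevalence in place — this inverse use is what the price policy needs.

## Scenarios

A scenario modifies the reference bundle's year-0 prevalence and/or its
transition rates; prevalence in later years is always an outcome of the
dynamics, never re-imposed.

* **Cessation** multiplies the odds of quitting: `q' = OR·o/(1 + OR·o)` with
  `o = q/(1-q)`, targeted at adults (default ages 18+). The odds scale is the
  standard reading of a cessation-trial odds ratio and approximately doubles
  small rates for OR 2.
* **Initiation** scales adolescent start rates by `1 - reduction` at school
  ages (default 10–18).
* **Price policy** converts a proportional price increase into prevalence
  reductions via price elasticities (defaults −0.7 up to age 20, −0.4 above,
  reflecting the greater price responsiveness of youth). Adults respond by
  quitting at once: the removed current-smoker mass enters `former_0` at year
  0 and their quit rates are untouched. Youths respond by not starting: their
  removed mass joins the never smokers, and adolescent start rates are
  re-derived from the scaled non-smoker curve so entering cohorts hold the
  post-intervention level. Restart rates are multiplied by a configurable
  factor at all ages.

**Reach** (the fraction of the target population actually exposed) mixes
treated and untreated rates linearly: `ρ·treated + (1-ρ)·untreated`. The
compartmental engine has no individual identity, so reach is deterministic
population mixing rather than a remembered subpopulation split; at `ρ = 0`
every scenario reproduces the reference exactly, and effects interpolate
linearly in between.

The shipped presets pin the three interventions in a *maximum* version
(idealised effect, 100% reach) and a *realistic* version (cessation reach
20% = 40% willingness × 50% participation; initiation reduction 20% at 50%
reach; price increase 20%). One documented tension: the preset price policy
cuts restart rates to 30% (maximum) / 80% (realistic) of reference, while the
stated rule "restart falls by the same proportion as the start rates" would
give multipliers of 0.335 / 0.86. The presets follow the pinned values; the
`restart_multiplier = "derived"` mode follows the rule. Which was intended is
not decidable from the available description, so both are exposed.

## Outcomes

* **Smoking prevalence series** collapse the time-since-quit classes to
  never/current/former, by year or by year × age. A subtlety: under a
  cessation intervention the never-smoker *counts* are exactly unchanged
  (nothing in the intervention touches them), but their *fraction* of the
  living population shifts in the fourth decimal because the intervention
  keeps more people alive — the denominator moves. The test suite asserts
  exact equality on counts.
* **Disease point prevalence** sums `count × prevalence` over cells;
  **at least one disease** uses the independence product
  `1 - prod_d(1 - p_d)` within each cell. Diseases evolve independently within
  a cell (no comorbidity correlation is modelled). The engine's survivor
  update uses the same independence assumption; mortality selection induces a
  small negative correlation between diseases that the compartmental engine
  ignores, which is one of the approximations the microsimulation comparison
  bounds in practice.
* **Excess deaths** are reported as scenario minus reference per calendar
  year, so deaths averted are negative.
* **Life expectancy** uses a period life table built from the projection
  year's own age-specific mortality (deaths over start-of-year population),
  with the midpoint half-year convention `L(a) = (l(a) + l(a+1))/2` and the
  top age closed (`q = 1`), so zero mortality gives exactly `age_max + 0.5`.
  "Healthy" life expectancy is implemented as **disease-free life
  expectancy** by the Sullivan method: person-years are weighted by the
  fraction free of *all* modelled diseases at each age. Outputs are labelled
  by that definition deliberately — no severity weighting is implied. Period
  (not cohort) tables are used because the reported quantities are snapshots
  at calendar years.

## The synthetic input bundle

The generator produces complete, validated input bundles with the statistical
structure of Dutch-like national inputs, so the entire pipeline is testable
without external data. All curves are smooth parametric shapes with small
seeded log-normal perturbations (σ = 0.02 on rate levels):

* population pyramid: logistic fade centred at age 72 (total ≈ 16 million at
  the default scale), constant future newborn counts;
* current-smoker prevalence: saturating uptake across ages 10–20, a plateau
  calibrated so the 18–65 mean hits the target (default 27%), declining after
  age ~60; former-smoker mass grows with age above 20 and shifts toward the
  open-ended time-since-quit class; below 21 all non-smokers are never
  smokers, matching the adolescent-survey convention;
* start rates on ages 10–19 derived from the uptake curve through the
  life-table identity (so the round trip is exact by construction), small
  tail to age 30; quit ≈ 3–8% per year rising with age; restart decaying from
  9% with age; all zero below the hand-off age;
* Gompertz mortality (log-hazard slope 0.095 per year, female rates scaled by
  0.65) plus a background hazard of 0.002 and a small infant term;
* three diseases on gamma-like incidence-by-age curves: lung-cancer-like
  (incidence RR 10, excess mortality 0.25/yr, short duration), COPD-like
  (RR 6, 0.03/yr), IHD-like (RR 2, 0.02/yr); baseline prevalence equals
  incidence × mean duration; female incidence scaled by 0.7;
* former-smoker RRs decay geometrically toward 1 with a 4-year half-life per
  time-since-quit class; all-cause RR 1.8 for current smokers.

The disease burden parameters were chosen so that the additive other-cause
decomposition is feasible with a comfortable margin at every age, sex, and
class (the binding constraint is mid-life, where total mortality is low but
disease prevalence has begun to rise); the generator re-checks feasibility on
every draw and refuses to emit an infeasible bundle.

What the generator does **not** emulate: real Dutch age patterns (cohort
effects, the historical smoking epidemic's sex difference in former smoking),
migration, trends in incidence or mortality, comorbidity correlation, and
measurement error structure. Passing the qualitative test suite on synthetic
data therefore shows that the *mechanics* — calibration, dynamics, scenario
transforms, accounting — are right, not that national projections are
reproduced. The published national headline values are shipped as documented
external-data targets (`dutch_headline_values()`): reproducing them requires
the national input database, which is not distributable with the package.

## Validation strategy

Because the engine is a deterministic expected-value model, it is validated
against an independent **person-level microsimulation** that applies the same
annual rules with Bernoulli draws per person. On the pinned fixture bundle
(ages 0–50, three time-since-quit classes, two diseases) with 10,000 persons
over 10 years, class occupancies and cumulative deaths must agree within 3
Monte-Carlo standard errors. Further anchors: mass conservation at every
step to 1e-9 relative; exact recovery of input RRs from year-1 incidence
ratios (1e-9); life-table round trips to 1e-12 over 1000 random monotone
curves; health-neutrality of smoking when all RRs are 1; and bit-exact
round trips of bundles and results through the CSV/JSON on-disk format
(numeric payloads are serialized with `%.17g` and parsed with a correctly
rounding reader).

Problem sizes in the shipped tests were chosen to keep the default suite
fast while leaving Monte-Carlo comparisons well-powered: the fixture bundle
for stochastic checks, the full 106-age bundle with a 40-year horizon for
the qualitative pattern suite, and 100 seeds for generator validity.

## Known limitations

* Rates are annual probabilities applied once per step, not hazards;
  competing events within a year are ordered, not simultaneous.
* No migration; newborns are the only inflow. No remission from any disease.
* Disease co-occurrence is independent within cells; "at least one disease"
  inherits that assumption.
* Reach has no memory: a person "reached" this year is not tracked as reached
  next year (the compartments carry no such identity).
* Combined interventions are out of scope: scenarios are compared one at a
  time against the reference.
* No uncertainty intervals are produced; the engine is deterministic and the
  input bundle carries no sampling variances.
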