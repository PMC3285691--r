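# smokesim

Dynamic multi-state simulation of tobacco control scenarios and their
long-term health impact.

## The problem

Policymakers choosing between tobacco control measures — helping smokers
quit, preventing adolescents from starting, or raising prices population-wide
— need quantitative projections of how each option changes future smoking
prevalence, chronic-disease burden, deaths, and healthy life expectancy, and
on what time scale. Those effects play out over decades through a causal
chain (exposure → disease incidence → disease prevalence → mortality) with
strong age structure and selective mortality, which intuition and static
attributable-fraction calculations handle poorly.

`smokesim` is a compartmental, Markov-type multi-state population model for
this kind of health impact assessment. It is aimed at epidemiologists and
HIA modellers who want a scriptable, fully tested engine with transparent
inputs.

## The model

The population is stratified by single year of age `a`, sex `s`, and smoking
class `c ∈ {never, current, former_k}` where `k` counts whole years since
quitting (the last class open-ended). Annual inputs, all by age and sex, are
the start/quit/restart probabilities, per-disease incidence–prevalence–excess
mortality (IPM) tables with incidence relative risks `RR_c(a)` per smoking
class, all-cause mortality `m(a,s)` with its own RRs, and demography.

Class-specific rates are calibrated so population-average inputs are
reproduced exactly: for each disease,

    I_never = I_pop / Σ_c w_c · RR_c ,   I_c = RR_c · I_never ,

with `w_c` the (reference) class shares; all-cause mortality is split the
same way, and each class's other-cause mortality is its class total minus its
disease-attributable part (additive mortality). Each projection year applies
smoking transitions, then disease incidence, then mortality, then ageing.
Adolescent initiation uses *net* start rates estimated from the non-smoker
prevalence curve via a cohort life table,
`s(a) = (p_ns(a) − p_ns(a+1)) / p_ns(a)`.

Interventions modify year-0 prevalence and/or transition rates relative to
the business-as-usual reference: a quit odds ratio (cessation), a
proportional start-rate reduction at school ages (initiation), or price
elasticities of prevalence with re-derived adolescent start rates and scaled
restart rates (price policy), each with a configurable population reach.
Outcomes include prevalence series, disease point prevalence, "at least one
disease" counts, excess deaths versus reference, and total and disease-free
(Sullivan) life expectancy. The methods vignette
(`vignettes/smoking-intervention-model.Rmd`) documents every assumption.

Because the national input database used in published applications is
external data, the package ships a synthetic-bundle generator
(`generate_bundle()`) that emulates the structure of Dutch-like inputs —
population pyramid, ~27% adult smoking, adolescent uptake at ages 10–20,
Gompertz mortality, gamma-like disease incidence with RRs 2–10 decaying with
time since quitting — plus a person-level microsimulation oracle used to
validate the deterministic engine.

## Worked example

```r
library(smokesim)

bundle <- generate_bundle(synthetic_config(seed = 1))
bundle
#> <smoking_bundle>
#>   baseline year: 2010
#>   ages: 0..105, time-since-quit classes: 11
#>   population: 16,232,756
#>   diseases: lung_cancer_like, copd_like, ihd_like

reference <- run_projection(bundle, scenario_spec("reference"), horizon = 25)
cessation <- run_projection(bundle, scenario_preset("cessation", "maximum"),
                            horizon = 25)

# current-smoker prevalence in 2035: quit-rate doubling accelerates the decline
sp  <- smoking_prevalence_series(reference)
spc <- smoking_prevalence_series(cessation)
round(100 * sp$value[sp$year == 2035 & sp$class == "current"], 1)   #> 14.5
round(100 * spc$value[spc$year == 2035 & spc$class == "current"], 1) #> 10.2

# prevalent cases averted by 2035 (difference = reference - scenario)
comparison_table(reference, cessation, years = 2035)
#> # A tibble: 4 × 5
#>    year outcome              reference scenario difference
#>   <dbl> <chr>                    <dbl>    <dbl>      <dbl>
#> 1  2035 lung_cancer_like        28612.   25156.      3456.
#> 2  2035 copd_like              305498.  289082.     16416.
#> 3  2035 ihd_like               629282.  623154.      6128.
#> 4  2035 at_least_one_disease   918608.  896767.     21841.

# disease-free life expectancy (Sullivan), and its gain under the scenario
round(life_expectancy(reference, 2010, "male", "disease_free"), 2)  #> 71.99
round(life_expectancy(cessation, 2034, "male", "disease_free") -
      life_expectancy(reference, 2034, "male", "disease_free"), 2)  #> 0.57
```

The prevalence numbers are fractions of the living population; the
comparison table counts prevalent cases at the start of the year, so the
`difference` column is cases averted by the intervention. All of this is on
the synthetic bundle — the shapes and orderings are meaningful, the absolute
national values are not (see `dutch_headline_values()` for the published
external-data targets and the vignette for what synthetic results do and do
not show).

## Analysis workflow

The `analysis/` scripts run the full study pipeline on the synthetic bundle
and write their outputs under `results/` (not versioned):

1. `01_build_inputs.R` — generate and validate the input bundle.
2. `02_project_scenarios.R` — 50-year projections for the reference and the
   three maximum-variant interventions; prevalence series and age profiles.
3. `03_health_outcomes.R` — disease-prevalence reductions at 2035/2060,
   excess deaths by year, life-expectancy tables.
4. `04_figures.R` — prevalence, age-profile, and excess-death figures.

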