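#!/usr/bin/env Rscript

# Reduce the projections to the reporting surfaces: disease point-prevalence
# reductions at 25 and 50 years, excess deaths by calendar year, and
# (disease-free) life expectancy per scenario.

suppressPackageStartupMessages({
  library(smokesim)
  library(readr)
})

runs <- lapply(c(reference = "reference", cessation_max = "cessation_max",
                 initiation_max = "initiation_max",
                 price_policy_max = "price_policy_max"),
               function(nm) read_results(file.path("results/runs", nm)))

dir.create("results/tables", showWarnings = FALSE, recursive = TRUE)

# disease-prevalence reductions vs reference (cases averted)
reductions <- do.call(rbind, lapply(
  c("cessation_max", "initiation_max", "price_policy_max"), function(nm) {
    tab <- comparison_table(runs$reference, runs[[nm]],
                            years = c(2035, 2060))
    tab$scenario <- nm
    tab
  }))
write_csv(reductions, "results/tables/disease_prevalence_reductions.csv")
message("cases averted at 2035 (at least one disease):")
sub <- reductions[reductions$year == 2035 &
                    reductions$outcome == "at_least_one_disease", ]
for (i in seq_len(nrow(sub))) {
  message(sprintf("  %-18s %8.0f", sub$scenario[i], sub$difference[i]))
}

# excess deaths by calendar year (negative = deaths averted)
excess <- do.call(rbind, lapply(
  c("cessation_max", "initiation_max", "price_policy_max"), function(nm) {
    ed <- excess_deaths_series(runs[[nm]], runs$reference)
    ed$scenario <- nm
    ed
  }))
write_csv(excess, "results/tables/excess_deaths_by_year.csv")

# life expectancy and disease-free life expectancy per scenario and snapshot
le <- do.call(rbind, lapply(names(runs), function(nm) {
  do.call(rbind, lapply(c(2010, 2035, 2059), function(y) {
    do.call(rbind, lapply(c("male", "female"), function(s) {
      data.frame(scenario = nm, year = y, sex = s,
                 life_expectancy = life_expectancy(runs[[nm]], y, s, "total"),
                 disease_free_le = life_expectancy(runs[[nm]], y, s,
                                                   "disease_free"))
    }))
  }))
}))
write_csv(le, "results/tables/life_expectancy.csv")
message(sprintf("disease-free LE 2035, male: reference %.2f, price policy %.2f",
                le$disease_free_le[le$scenario == "reference" & le$year == 2035 & le$sex == "male"],
                le$disease_free_le[le$scenario == "price_policy_max" & le$year == 2035 & le$sex == "male"]))
message("tables written to results/tables/")
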