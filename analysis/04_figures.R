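#!/usr/bin/env Rscript

# Figures: smoking prevalence over time per scenario, age profiles of former
# smokers under the price policy, and excess deaths by calendar year.

suppressPackageStartupMessages({
  library(readr)
  library(ggplot2)
})

dir.create("results/figures", showWarnings = FALSE, recursive = TRUE)

series <- read_csv("results/series/smoking_prevalence_by_year.csv",
                   show_col_types = FALSE)
p1 <- ggplot(series, aes(year, value, colour = scenario)) +
  geom_line() +
  facet_wrap(~class) +
  labs(y = "prevalence (fraction of population)",
       title = "Smoking-state prevalence over time by scenario") +
  theme_minimal()
ggsave("results/figures/prevalence_over_time.pdf", p1, width = 9, height = 4)

profiles <- read_csv("results/series/smoking_prevalence_by_age.csv",
                     show_col_types = FALSE)
former <- profiles[profiles$class == "former" &
                     profiles$scenario %in% c("reference",
                                              "price_policy_max"), ]
p2 <- ggplot(former, aes(age, value, colour = scenario)) +
  geom_line() +
  facet_wrap(~year, nrow = 1) +
  labs(y = "former-smoker prevalence",
       title = "Former smokers by age: price policy vs reference") +
  theme_minimal()
ggsave("results/figures/former_by_age.pdf", p2, width = 10, height = 3.5)

excess <- read_csv("results/tables/excess_deaths_by_year.csv",
                   show_col_types = FALSE)
p3 <- ggplot(excess, aes(year, excess_deaths, colour = scenario)) +
  geom_hline(yintercept = 0, linetype = 2) +
  geom_line() +
  labs(y = "deaths vs reference (negative = averted)",
       title = "Difference in deaths by calendar year") +
  theme_minimal()
ggsave("results/figures/excess_deaths.pdf", p3, width = 7, height = 4)

message("figures written to results/figures/")
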