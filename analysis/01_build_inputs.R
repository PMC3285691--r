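#!/usr/bin/env Rscript

# Build the synthetic Dutch-like input bundle that stands in for the national
# data (smoking prevalence and transition probabilities, disease IPM tables,
# relative risks, demography) and write it to results/bundle/.

suppressPackageStartupMessages(library(smokesim))

cfg <- synthetic_config(seed = 1L)
bundle <- generate_bundle(cfg)

stopifnot(nrow(validate_bundle(bundle)) == 0)
write_bundle(bundle, "results/bundle")

adult <- 0:bundle$age_max >= 18 & 0:bundle$age_max <= 65
message(sprintf("population: %.1f million", sum(bundle$demography$population) / 1e6))
message(sprintf("adult (18-65) current-smoker prevalence: %.1f%% (target %.0f%%)",
                100 * mean(bundle$smoking[adult, , 2]), 100 * cfg$smoking_target))
message(sprintf("diseases: %s",
                paste(names(bundle$diseases), collapse = ", ")))
message("bundle written to results/bundle/")
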