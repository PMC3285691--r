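Package: smokesim
Title: Dynamic Multi-State Simulation of Tobacco Control Scenarios
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A compartmental, Markov-type multi-state population model for
    health impact assessment of tobacco control interventions. Projects
    smoking-state prevalence (never, current, and former smokers by time since
    quitting), smoking-related disease prevalence, deaths, and (disease-free)
    life expectancy under a business-as-usual reference scenario and under
    cessation, initiation-prevention, and price-policy intervention scenarios.
    Includes a life-table estimator of net adolescent initiation rates, a
    synthetic input-bundle generator emulating Dutch-like national data, and a
    seeded person-level microsimulation oracle used to validate the
    compartmental engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    readr,
    stats,
    tibble,
    tools,
    utils
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
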