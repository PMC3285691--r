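test_that("prevalence series start at the input distribution and sum to 1", {
  b <- small_fixture()
  r <- run_projection(b, horizon = 5)
  sp <- smoking_prevalence_series(r)
  sums <- tapply(sp$value, sp$year, sum)
  expect_equal(as.vector(sums), rep(1, 6), tolerance = 1e-12)

  # year 0 must equal the (population-weighted) input prevalence
  pop <- b$demography$population
  w_current <- sum(b$smoking[, , 2] * pop) / sum(pop)
  expect_equal(sp$value[sp$year == 2010 & sp$class == "current"], w_current,
               tolerance = 1e-12)

  # scenario-modified year 0: the price shock is visible immediately
  pri <- run_projection(b, scenario_preset("price_policy", "maximum"),
                        horizon = 0)
  spp <- smoking_prevalence_series(pri)
  expect_lt(spp$value[spp$class == "current"], w_current)
})

test_that("disease prevalence with zero incidence only decays", {
  b <- tiny_bundle(age_max = 20, inc = 0, prev = 0.2, em = 0.05,
                   m_total = 0.02, newborns = 0)
  r <- run_projection(b, horizon = 8)
  counts <- vapply(r$years, disease_point_prevalence, 0, result = r,
                   disease = "d1")
  expect_true(all(diff(counts) < 0))
  expect_true(all(vapply(r$new_cases, sum, 0) == 0))
  expect_error(disease_point_prevalence(r, 2005, "d1"), "outside")
  expect_error(disease_point_prevalence(r, 2012, "nope"), "unknown disease")
})

test_that("at-least-one-disease uses the independence product", {
  b <- tiny_bundle(n_diseases = 2L, prev = 0) # set prevalences by hand
  b$diseases$d1$prevalence[] <- 0.1
  b$diseases$d2$prevalence[] <- 0.2
  r <- run_projection(b, horizon = 0)
  expect_equal(at_least_one_disease(r, 2010),
               (1 - 0.9 * 0.8) * sum(b$demography$population),
               tolerance = 1e-12)

  b1 <- tiny_bundle(n_diseases = 1L, prev = 0.13)
  r1 <- run_projection(b1, horizon = 0)
  expect_equal(at_least_one_disease(r1, 2010),
               disease_point_prevalence(r1, 2010, "d1"), tolerance = 1e-12)

  b0 <- tiny_bundle(n_diseases = 0L)
  r0 <- run_projection(b0, horizon = 0)
  expect_equal(at_least_one_disease(r0, 2010), 0)
})

test_that("excess deaths difference is zero for reference vs itself and closes the population balance", {
  runs <- dutch_runs()
  self <- excess_deaths_series(runs$ref, runs$ref)
  expect_equal(self$excess_deaths, rep(0, nrow(self)))

  ed <- excess_deaths_series(runs$ces, runs$ref)
  # closed population: the scenario's population surplus equals the averted
  # deaths minus the extra top-age exits, cumulated
  for (i in c(5, 15, 30)) {
    surplus <- total_pop(runs$ces, i + 1) - total_pop(runs$ref, i + 1)
    exits_diff <- sum(runs$ces$exits[1:i, ]) - sum(runs$ref$exits[1:i, ])
    expect_equal(surplus, -sum(ed$excess_deaths[1:i]) - exits_diff,
                 tolerance = 1e-6)
  }

  short <- run_projection(dutch_bundle(), horizon = 2)
  expect_error(excess_deaths_series(short, runs$ref), "horizon")
})

test_that("period life expectancy matches closed forms", {
  # q = 1/2 at every age: e0 = sum over a of 0.75 * 0.5^a -> 1.5
  expect_equal(period_life_expectancy(rep(0.5, 200)), 1.5, tolerance = 1e-10)
  # zero mortality up to the (closed) top age
  expect_equal(period_life_expectancy(rep(0, 51)), 50.5)
  # weights of 1 are the default
  expect_equal(period_life_expectancy(rep(0.1, 80), rep(1, 80)),
               period_life_expectancy(rep(0.1, 80)))
})

test_that("disease-free life expectancy is bounded by total life expectancy", {
  runs <- dutch_runs()
  for (y in c(2010, 2025)) {
    for (s in c("male", "female")) {
      le <- life_expectancy(runs$ref, y, s, "total")
      dfle <- life_expectancy(runs$ref, y, s, "disease_free")
      expect_lt(dfle, le)
      expect_gt(dfle, 40) # sanity: an industrialised-country magnitude
    }
  }
  expect_error(life_expectancy(runs$ref, max(runs$ref$years), "male"),
               "final projection year")
})

test_that("disease-free life expectancy falls when prevalence is perturbed up", {
  runs <- dutch_runs()
  r2 <- runs$ref
  i <- match(2020, r2$years)
  base <- life_expectancy(r2, 2020, "male", "disease_free")
  r2$prev[[i]][, , , 1] <- pmin(r2$prev[[i]][, , , 1] + 0.05, 1)
  expect_lt(life_expectancy(r2, 2020, "male", "disease_free"), base)
  # total LE is built from deaths only and must be unaffected
  expect_equal(life_expectancy(r2, 2020, "male", "total"),
               life_expectancy(runs$ref, 2020, "male", "total"))
})

test_that("comparison tables satisfy reference = scenario + difference", {
  runs <- dutch_runs()
  tab <- comparison_table(runs$ref, runs$ces, years = c(2025, 2035))
  expect_setequal(unique(tab$outcome),
                  c(runs$ref$disease_names, "at_least_one_disease"))
  expect_equal(tab$reference, tab$scenario + tab$difference)
  self <- comparison_table(runs$ref, runs$ref, years = 2025)
  expect_equal(self$difference, rep(0, nrow(self)))
})
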