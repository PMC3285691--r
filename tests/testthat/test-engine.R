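test_that("class-specific incidence calibration reproduces the population rate", {
  inc <- calibrate_class_specific_incidence(
    0.001, shares = c(0.5, 0.3, 0.2), rr = c(1, 10, 4))
  expect_equal(inc[1], 0.001 / 4.3, tolerance = 1e-12)
  expect_equal(inc[2], 0.01 / 4.3, tolerance = 1e-12)
  expect_equal(sum(c(0.5, 0.3, 0.2) * inc), 0.001, tolerance = 1e-15)

  # neutral relative risks leave the population rate untouched
  expect_equal(calibrate_class_specific_incidence(0.02, c(0.1, 0.7, 0.2),
                                                  c(1, 1, 1)),
               rep(0.02, 3))
  # single-class population: that class must carry the population rate
  inc1 <- calibrate_class_specific_incidence(0.005, c(0, 1, 0), c(1, 10, 4))
  expect_equal(inc1[2], 0.005)
  expect_equal(inc1[1], 0.0005)

  expect_error(calibrate_class_specific_incidence(0.01, c(1, 0), c(0, 5)),
               "degenerate")
})

test_that("additive mortality decomposition subtracts and guards feasibility", {
  expect_equal(derive_other_cause_mortality(0.010, 0.004), 0.006)
  expect_equal(derive_other_cause_mortality(0.010, 0), 0.010)
  expect_error(derive_other_cause_mortality(0.01, 0.02, where = "age 40"),
               "age 40")
})

test_that("state-specific mortality preserves the all-cause mean and RRs", {
  m <- derive_state_specific_mortality(0.02, rr_allcause = c(1, 3),
                                       shares = c(0.5, 0.5))
  expect_equal(m$total, c(0.01, 0.03))
  expect_equal(sum(c(0.5, 0.5) * m$total), 0.02, tolerance = 1e-15)

  # neutral RRs: every class inherits the total rate
  m1 <- derive_state_specific_mortality(0.013, c(1, 1, 1),
                                        c(0.2, 0.5, 0.3))
  expect_equal(m1$total, rep(0.013, 3))

  # conservation contract holds for arbitrary valid inputs
  set.seed(7)
  for (i in 1:200) {
    n <- sample(2:6, 1)
    sh <- runif(n); sh <- sh / sum(sh)
    rr <- c(1, runif(n - 1, 0.5, 5))
    mt <- runif(1, 0, 0.5)
    m <- derive_state_specific_mortality(mt, rr, sh)
    expect_lt(abs(sum(sh * m$total) - mt), 1e-14)
    expect_equal(m$total[2] / m$total[1], rr[2], tolerance = 1e-12)
  }

  expect_error(
    derive_state_specific_mortality(0.01, c(1, 2), c(0.9, 0.1),
                                    disease_mortality_by_class = c(0.02, 0)),
    "inconsistent")
})

test_that("a step with all rates zero is a pure age shift plus newborns", {
  # no former mass, so the time-since-quit clock has nothing to advance
  b <- tiny_bundle(shares = c(0.7, 0.3, 0), newborns = 17)
  model <- compile_model(b)
  st <- initial_state(b)
  out <- step_year(st, model, newborns = c(17, 17))
  expect_equal(out$deaths, matrix(0, 6, 2), ignore_attr = TRUE)
  expect_equal(out$state$count[2:6, , ], st$count[1:5, , ],
               ignore_attr = TRUE)
  expect_equal(unname(out$state$count[1, , 1]), c(17, 17))
  expect_equal(sum(out$state$count[1, , 2:4]), 0)
  expect_equal(unname(out$exits), unname(rowSums(st$count[6, , ])))

  # with former mass, only the time-since-quit clock moves: class aggregates
  # are still a pure age shift
  b2 <- tiny_bundle(shares = c(0.6, 0.3, 0.1))
  st2 <- initial_state(b2)
  out2 <- step_year(st2, compile_model(b2), newborns = c(0, 0))
  expect_equal(out2$state$count[2:6, , 1:2], st2$count[1:5, , 1:2],
               ignore_attr = TRUE)
  expect_equal(rowSums(out2$state$count[2:6, , 3:4], dims = 2),
               rowSums(st2$count[1:5, , 3:4], dims = 2), ignore_attr = TRUE)
  # the top class is absorbing, the first former class drains
  expect_equal(sum(out2$state$count[2:6, , 3]), 0)
})

test_that("population mass is conserved at every step", {
  b <- generate_bundle(synthetic_config(seed = 3, age_max = 60,
                                        population_scale = 1000))
  r <- run_projection(b, scenario_preset("price_policy", "maximum"),
                      horizon = 8)
  nb <- b$demography$newborns
  for (t in 1:8) {
    expected <- total_pop(r, t) - sum(r$deaths[t, , ]) - sum(r$exits[t, ]) +
      sum(nb[min(t, nrow(nb)), ])
    expect_equal(total_pop(r, t + 1), expected,
                 tolerance = 1e-9)
    # occupancies stay non-negative, so class fractions remain a
    # probability distribution
    expect_true(all(r$counts[[t + 1]] >= 0))
  }
})

test_that("the engine is deterministic", {
  b <- small_fixture()
  r1 <- run_projection(b, scenario_preset("cessation", "maximum"),
                       horizon = 5)
  r2 <- run_projection(b, scenario_preset("cessation", "maximum"),
                       horizon = 5)
  expect_identical(r1$counts, r2$counts)
  expect_identical(r1$deaths, r2$deaths)
})

test_that("with all relative risks 1, smoking is health-neutral", {
  b <- tiny_bundle(age_max = 30, k = 2, shares = c(0.5, 0.4, 0.1),
                   start = 0.02, quit = 0.05, restart = 0.03,
                   m_total = 0.02, rr_allcause = 1,
                   inc = 0.01, prev = 0.05, em = 0.005, rr_inc = 1,
                   newborns = 10)
  ref <- run_projection(b, scenario_spec("reference"), horizon = 10)
  ces <- run_projection(b, scenario_spec("cessation", quit_or = 3,
                                         target_ages = c(0, Inf)),
                        horizon = 10)
  # smoking exposure differs ...
  expect_false(isTRUE(all.equal(ref$counts[[11]], ces$counts[[11]])))
  # ... but deaths and disease burden are identical
  expect_equal(ces$deaths, ref$deaths, tolerance = 1e-12)
  for (y in ref$years) {
    expect_equal(disease_point_prevalence(ces, y, "d1"),
                 disease_point_prevalence(ref, y, "d1"), tolerance = 1e-12)
  }
})

test_that("year-1 incidence ratios recover the configured relative risk", {
  # transitions zeroed so the at-risk denominators stay at their baseline
  # values; the incidence ratio current vs never must equal rr_current
  b <- dutch_bundle()
  b$rates$start[] <- 0
  b$rates$quit[] <- 0
  b$rates$restart[] <- 0
  r <- run_projection(b, scenario_spec("reference"), horizon = 1)
  cnt <- r$counts[[1]]
  for (j in seq_along(r$disease_names)) {
    d <- b$diseases[[j]]
    cases <- r$new_cases[[1]][, , , j]
    at_risk <- cnt * (1 - array(d$prevalence, dim = dim(cnt)))
    sel <- at_risk[, , 1] > 1 & at_risk[, , 2] > 1 & cases[, , 1] > 0
    rate_never <- cases[, , 1][sel] / at_risk[, , 1][sel]
    rate_current <- cases[, , 2][sel] / at_risk[, , 2][sel]
    rr_expected <- matrix(rep(d$rr_current, 2), ncol = 2)[sel]
    expect_gt(length(rate_never), 50)
    expect_equal(rate_current / rate_never, rr_expected, tolerance = 1e-9)
  }
})
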