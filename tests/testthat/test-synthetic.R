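test_that("the generator is deterministic in its seed", {
  b1 <- generate_bundle(synthetic_config(seed = 5))
  b2 <- generate_bundle(synthetic_config(seed = 5))
  expect_equal(b1, b2, tolerance = 0)
  b3 <- generate_bundle(synthetic_config(seed = 6))
  expect_false(isTRUE(all.equal(b1$rates$quit, b3$rates$quit)))
})

test_that("generated bundles are valid and on-target across many seeds", {
  for (seed in 1:100) {
    cf <- synthetic_config(seed = seed, age_max = 70,
                           population_scale = 1000)
    b <- generate_bundle(cf)
    expect_identical(nrow(validate_bundle(b)), 0L)
    adult <- 0:70 >= 18 & 0:70 <= 65
    expect_lt(abs(mean(b$smoking[adult, , 2]) - cf$smoking_target), 0.02)
  }
})

test_that("a zero smoking target produces a degenerate smoke-free bundle", {
  b <- generate_bundle(synthetic_config(seed = 1, smoking_target = 0))
  expect_equal(sum(b$smoking[, , -1]), 0)
  expect_true(all(b$smoking[, , 1] == 1))
  expect_equal(sum(b$rates$start) + sum(b$rates$quit) + sum(b$rates$restart),
               0)
})

test_that("generated RRs decay monotonically and start rates obey the life-table identity", {
  b <- dutch_bundle()
  for (d in b$diseases) {
    expect_true(all(diff(t(d$rr_former)) <= 1e-12))
    expect_true(all(d$rr_former >= 1 - 1e-12))
    expect_true(all(d$rr_former <= rep(d$rr_current, b$k_classes) + 1e-12))
  }
  # adolescent never-smoker curve reproduced by the start rates
  ages <- 0:b$age_max
  win <- ages >= 10 & ages <= 20
  for (s in 1:2) {
    p <- b$smoking[win, s, 1]
    rates <- b$rates$start[win, s][-sum(win)]
    expect_equal(forward_cohort(p[1], rates), unname(p), tolerance = 1e-12)
  }
})

test_that("class-calibrated incidence averages back to the generated population incidence", {
  b <- dutch_bundle()
  model <- compile_model(b)
  for (j in seq_along(b$diseases)) {
    for (s in 1:2) {
      pop_inc <- rowSums(b$smoking[, s, ] * model$inc[, s, , j])
      expect_equal(pop_inc, unname(b$diseases[[j]]$incidence[, s]),
                   tolerance = 1e-12, ignore_attr = TRUE)
    }
  }
})

test_that("the pinned fixture bundle has not drifted", {
  fb <- small_fixture()
  expect_equal(sum(fb$demography$population), 407228.2532, tolerance = 1e-6)
  expect_equal(fb$demography$population["30", "male"], 3962.736163,
               tolerance = 1e-6)
  expect_equal(fb$smoking["25", "female", "current"], 0.2744054874,
               tolerance = 1e-6)
  expect_equal(fb$rates$quit["40", "male"], 0.03821403856, tolerance = 1e-6)
  expect_equal(fb$diseases$lung_cancer_like$incidence["45", "male"],
               0.001982855144, tolerance = 1e-6)
  r10 <- run_projection(fb, horizon = 10)
  expect_equal(sum(r10$deaths), 10375.79535, tolerance = 1e-6)
  expect_equal(sum(r10$counts[[11]][, , 2]), 68860.21725, tolerance = 1e-6)
})

test_that("the microsimulation is exact when nothing can happen", {
  # all rates and mortality zero: nobody dies or changes never/current state;
  # former smokers only advance their time-since-quit clock
  b <- tiny_bundle(age_max = 30)
  b$demography$newborns[] <- 0
  ms <- microsim_oracle(b, n_persons = 500, seed = 3, horizon = 5)
  expect_true(all(ms$deaths == 0))
  agg <- cbind(ms$class_counts[, 1:2], former = rowSums(ms$class_counts[, 3:4]))
  for (t in 2:6) {
    expect_true(all(agg[t, ] <= agg[1, ]))
    expect_equal(sum(agg[t, ]), sum(agg[1, ]) - sum(ms$exits[seq_len(t - 1)]))
  }
  # with no top age reachable within the horizon, aggregates are frozen and
  # all former mass drains into the absorbing top class
  b2 <- tiny_bundle(age_max = 30)
  b2$demography$population[25:31, ] <- 0 # nobody close to the top age
  b2$demography$newborns[] <- 0
  ms2 <- microsim_oracle(b2, n_persons = 500, seed = 3, horizon = 5)
  agg2 <- cbind(ms2$class_counts[, 1:2],
                former = rowSums(ms2$class_counts[, 3:4]))
  expect_true(all(agg2 == rep(agg2[1, ], each = 6)))
  expect_equal(unname(ms2$class_counts[6, 3]), 0)
  expect_equal(unname(ms2$class_counts[6, 4]), unname(agg2[1, "former"]))
})

test_that("microsimulation error scales as 1/sqrt(n)", {
  b <- small_fixture()
  b$demography$newborns[] <- 0
  frac_current <- function(n, seed) {
    ms <- microsim_oracle(b, n_persons = n, seed = seed, horizon = 3)
    ms$class_counts[4, 2] / sum(ms$class_counts[4, ])
  }
  reps <- 40
  est_small <- vapply(1:reps, function(i) frac_current(400, i), 0)
  est_big <- vapply(1:reps, function(i) frac_current(800, 1000 + i), 0)
  ratio <- sd(est_small) / sd(est_big)
  expect_gt(ratio, 1.05)
  expect_lt(ratio, 1.95)
})
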