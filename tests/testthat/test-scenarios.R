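ast_rate <- function(x, age_max = 40) {
  matrix(x, age_max + 1, 2,
         dimnames = list(age = 0:age_max, sex = c("male", "female")))
}

test_that("the cessation odds-ratio transform works on the odds scale", {
  q <- ast_rate(0.05)
  out <- transform_quit_rates_or(q, quit_or = 2, reach = 1,
                                 target_ages = c(18, Inf))
  # odds 0.05/0.95 doubled and back-transformed: exactly 2/21
  expect_equal(out["30", "male"], 2 / 21, tolerance = 1e-12)
  expect_equal(out["30", "male"], 0.0952381, tolerance = 1e-6)
  # roughly a doubling for small rates
  expect_equal(out["30", "male"] / 0.05, 2, tolerance = 0.05)
  # untouched outside the target ages
  expect_equal(out["17", "male"], 0.05)

  # identity OR
  expect_equal(transform_quit_rates_or(q, 1, 1, c(0, Inf)), q)

  # 20% reach mixes treated and untreated rates
  out20 <- transform_quit_rates_or(q, 2, reach = 0.2,
                                   target_ages = c(18, Inf))
  expect_equal(out20["30", "female"], 0.2 * 2 / 21 + 0.8 * 0.05,
               tolerance = 1e-12)
  expect_equal(out20["30", "female"], 0.0590476, tolerance = 1e-6)

  expect_error(transform_quit_rates_or(ast_rate(1), 2), "odds")
})

test_that("the initiation transform scales start rates in the target window", {
  s <- ast_rate(0.04)
  expect_equal(
    transform_start_rates(s, 0.5, 1, c(10, 18))["15", "male"], 0.02)
  expect_equal(
    transform_start_rates(s, 0.2, 0.5, c(10, 18))["15", "male"], 0.036)
  expect_equal(transform_start_rates(s, 0, 1, c(10, 18)), s)
  expect_equal(
    transform_start_rates(s, 0.5, 1, c(10, 18))["19", "male"], 0.04)
})

test_that("price elasticities give the documented prevalence reductions", {
  expect_equal(prevalence_reduction_from_price(0.95, -0.7), 0.665)
  expect_equal(prevalence_reduction_from_price(0.95, -0.4), 0.38)
  expect_equal(prevalence_reduction_from_price(0.20, -0.7), 0.14)
  expect_equal(prevalence_reduction_from_price(0.20, -0.4), 0.08)
  expect_error(prevalence_reduction_from_price(2, -0.7), "100%")
})

test_that("the price policy shifts prevalence mass and rescales rates", {
  b <- dutch_bundle()
  spec <- scenario_preset("price_policy", "maximum")
  out <- apply_price_policy(b, spec)
  ages <- 0:b$age_max
  youth <- ages <= 20
  adult <- !youth

  # youth smokers scaled by 1 - 0.665, mass moved to never
  expect_equal(out$smoking[youth, , 2], b$smoking[youth, , 2] * 0.335,
               tolerance = 1e-12)
  expect_equal(out$smoking[youth, , 1],
               b$smoking[youth, , 1] + b$smoking[youth, , 2] * 0.665,
               tolerance = 1e-12)
  # adult smokers scaled by 1 - 0.38, mass moved to former_0
  expect_equal(out$smoking[adult, , 2], b$smoking[adult, , 2] * 0.62,
               tolerance = 1e-12)
  expect_equal(out$smoking[adult, , 3],
               b$smoking[adult, , 3] + b$smoking[adult, , 2] * 0.38,
               tolerance = 1e-12)
  # distributions still normalised
  expect_true(all(abs(apply(out$smoking, c(1, 2), sum) - 1) < 1e-9))
  # restart rates cut to the preset multiplier, quit rates untouched
  expect_equal(out$rates$restart, b$rates$restart * 0.30)
  expect_equal(out$rates$quit, b$rates$quit)
  expect_equal(scenario_preset("price_policy", "realistic")$restart_multiplier,
               0.80)

  # "derived" mode ties restart to the youth start-rate reduction instead
  spec_d <- scenario_spec("price_policy", price_increase = 0.95)
  out_d <- apply_price_policy(b, spec_d)
  expect_equal(out_d$rates$restart, b$rates$restart * 0.335,
               tolerance = 1e-12)

  # zero price increase is the identity
  expect_equal(
    apply_price_policy(b, scenario_spec("price_policy", price_increase = 0)),
    b)
})

test_that("scenario dispatch touches exactly the advertised components", {
  b <- dutch_bundle()
  expect_identical(build_scenario_bundle(b, scenario_spec("reference")), b)

  ces <- build_scenario_bundle(b, scenario_preset("cessation", "maximum"))
  expect_equal(ces$smoking, b$smoking)
  expect_equal(ces$rates$start, b$rates$start)
  expect_equal(ces$rates$restart, b$rates$restart)
  ages <- 0:b$age_max
  expect_equal(ces$rates$quit[ages < 18, ], b$rates$quit[ages < 18, ])
  expect_false(isTRUE(all.equal(ces$rates$quit[ages >= 18, ],
                                b$rates$quit[ages >= 18, ])))

  ini <- build_scenario_bundle(b, scenario_preset("initiation", "maximum"))
  expect_equal(ini$smoking, b$smoking) # year-0 prevalence untouched
  expect_equal(ini$rates$quit, b$rates$quit)
  expect_equal(ini$rates$restart, b$rates$restart)
  touched <- ages >= 10 & ages <= 18
  expect_equal(ini$rates$start[!touched, ], b$rates$start[!touched, ])
  expect_equal(ini$rates$start[touched, ], b$rates$start[touched, ] * 0.5)
})

test_that("reach interpolates linearly between reference and full effect", {
  q <- ast_rate(0.07)
  full <- transform_quit_rates_or(q, 2, reach = 1, target_ages = c(0, Inf))
  for (rho in c(0, 0.25, 0.5, 0.9)) {
    mixed <- transform_quit_rates_or(q, 2, reach = rho,
                                     target_ages = c(0, Inf))
    expect_equal(mixed, rho * full + (1 - rho) * q, tolerance = 1e-12)
  }
  # at reach 0 every scenario collapses to the reference
  b <- small_fixture()
  ces0 <- build_scenario_bundle(
    b, scenario_spec("cessation", quit_or = 2, reach = 0))
  expect_equal(ces0, b)
  ini0 <- build_scenario_bundle(
    b, scenario_spec("initiation", start_reduction = 0.5, reach = 0))
  expect_equal(ini0, b)
})

test_that("person-years of smoking averted order as price > cessation > initiation", {
  runs <- dutch_runs()
  py_current <- function(r) {
    sum(vapply(2:16, function(i) sum(r$counts[[i]][, , 2]), 0))
  }
  averted <- vapply(runs[c("pri", "ces", "ini")],
                    function(r) py_current(runs$ref) - py_current(r), 0)
  expect_true(averted[["pri"]] > averted[["ces"]])
  expect_true(averted[["ces"]] > averted[["ini"]])
  expect_true(averted[["ini"]] > 0)
})
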