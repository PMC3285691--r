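# Shared fixtures, built in code and memoised across test files.

.test_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .test_cache)) {
    assign(name, force(expr), envir = .test_cache)
  }
  get(name, envir = .test_cache)
}

# Dutch-like synthetic bundle and the four maximum-variant runs used by the
# scenario-ordering and pattern tests.
dutch_bundle <- function() {
  cached("dutch_bundle", generate_bundle(synthetic_config(seed = 1L)))
}

dutch_runs <- function(horizon = 40L) {
  cached("dutch_runs", {
    b <- dutch_bundle()
    list(
      ref = run_projection(b, scenario_spec("reference"), horizon = horizon),
      ces = run_projection(b, scenario_preset("cessation", "maximum"),
                           horizon = horizon),
      ini = run_projection(b, scenario_preset("initiation", "maximum"),
                           horizon = horizon),
      pri = run_projection(b, scenario_preset("price_policy", "maximum"),
                           horizon = horizon)
    )
  })
}

small_fixture <- function() cached("fixture", fixture_bundle())

# Miniature hand-built bundle with uniform rates; every knob is a scalar so
# expected engine behaviour can be computed by hand.
tiny_bundle <- function(age_max = 5L, k = 2L,
                        shares = c(0.6, 0.3, 0.1),
                        start = 0, quit = 0, restart = 0,
                        m_total = 0, rr_allcause = 1,
                        inc = 0, prev = 0, em = 0, rr_inc = 1,
                        pop = 100, newborns = 0, n_diseases = 1L) {
  n_age <- age_max + 1L
  sexes <- c("male", "female")
  ast <- function(x) matrix(x, n_age, 2,
                            dimnames = list(age = 0:age_max, sex = sexes))
  nc <- k + 2L
  smoking <- array(0, c(n_age, 2L, nc),
                   dimnames = list(age = 0:age_max, sex = sexes,
                                   class = smoking_classes(k)))
  smoking[, , 1] <- shares[1]
  smoking[, , 2] <- shares[2]
  for (j in 3:nc) smoking[, , j] <- shares[3] / k
  rr_decay <- function(rr) {
    matrix(1 + (rr - 1) * 0.5^(seq_len(k)), n_age, k, byrow = TRUE)
  }
  diseases <- list()
  for (i in seq_len(n_diseases)) {
    nm <- paste0("d", i)
    diseases[[nm]] <- disease_definition(
      nm, ast(inc), ast(prev), ast(em),
      rr_current = rep(rr_inc, n_age), rr_former = rr_decay(rr_inc))
  }
  smoking_bundle(
    demography = list(
      population = ast(pop),
      newborns = matrix(newborns, 5, 2, dimnames = list(NULL, sexes))),
    smoking = smoking,
    rates = list(start = ast(start), quit = ast(quit), restart = ast(restart)),
    diseases = diseases,
    mortality = list(m_total = ast(m_total),
                     rr_current = rep(rr_allcause, n_age),
                     rr_former = rr_decay(rr_allcause)),
    age_max = age_max, k_classes = k, validate = TRUE
  )
}

# Independent forward life-table oracle (deliberately a plain loop, not the
# package's vectorised implementation).
forward_cohort <- function(p0, rates) {
  l <- numeric(length(rates) + 1)
  l[1] <- p0
  for (i in seq_along(rates)) l[i + 1] <- l[i] * (1 - rates[i])
  l
}

total_pop <- function(result, i) sum(result$counts[[i]])
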