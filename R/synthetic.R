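# Run code under a local RNG seed without disturbing the caller's RNG state.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Configuration for the synthetic input-bundle generator
#'
#' Describes a stylised national population with Dutch-like structure: a
#' smooth population pyramid; adult current-smoker prevalence around the
#' target (default 27%, declining at old age); adolescent uptake concentrated
#' in the 10-20 window; Gompertz-type all-cause mortality; disease incidence
#' rising with age on gamma-like curves; and incidence relative risks that are
#' high for current smokers and decay geometrically toward 1 with time since
#' quitting. All curves are smooth parametric shapes, not resampled data, so
#' the ground truth is fully controlled.
#'
#' @param seed Integer seed; the same configuration and seed always produce an
#'   identical bundle.
#' @param age_max,k_classes,baseline_year Bundle dimensions (see
#'   [smoking_bundle()]).
#' @param population_scale Population count scale: persons per sex at age 0.
#'   The default yields a total population of roughly 16 million, so absolute
#'   outputs have national order of magnitude.
#' @param smoking_target Mean current-smoker prevalence over ages 18-65 (both
#'   sexes); 0 produces a degenerate smoke-free bundle with all transition
#'   rates 0.
#' @param uptake_ages Adolescent uptake window (inclusive); start rates inside
#'   it are derived from the prevalence curve via the life-table identity.
#' @param gompertz List with `modal_rate` (hazard scale), `slope` (log-hazard
#'   increase per year of age), `background` (age-independent hazard), and
#'   `female_factor` (< 1; women die at lower rates).
#' @param diseases List of per-disease parameter lists with fields `name`,
#'   `inc_max` (peak population incidence), `onset`, `peak` (ages), `duration`
#'   (mean years with disease, sets baseline prevalence), `excess_mortality`
#'   (annual death probability added among the diseased), `rr_current`, and
#'   `female_factor`. Defaults: a lung-cancer-like disease (RR 10), a
#'   COPD-like disease (RR 6), and an IHD-like disease (RR 2).
#' @param rr_allcause_current Relative risk of current smoking on all-cause
#'   mortality.
#' @param rr_halflife Half-life, in years since quitting, of the excess
#'   relative risk: `rr_k = 1 + (rr_current - 1) * 0.5^(k / rr_halflife)`.
#' @param noise_sd Standard deviation of the seeded log-normal perturbations
#'   applied to rate levels (small, so invariants hold for any seed).
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L, age_max = 105L, k_classes = 11L,
                             baseline_year = 2010L,
                             population_scale = 110000,
                             smoking_target = 0.27,
                             uptake_ages = c(10L, 20L),
                             gompertz = list(modal_rate = 2.2e-5,
                                             slope = 0.095,
                                             background = 0.002,
                                             female_factor = 0.65),
                             diseases = default_disease_params(),
                             rr_allcause_current = 1.8,
                             rr_halflife = 4,
                             noise_sd = 0.02) {
  stopifnot(smoking_target >= 0, smoking_target <= 0.6,
            uptake_ages[1] >= 0, uptake_ages[2] <= age_max,
            rr_allcause_current >= 0, rr_halflife > 0, noise_sd >= 0)
  structure(
    list(seed = as.integer(seed), age_max = as.integer(age_max),
         k_classes = as.integer(k_classes),
         baseline_year = as.integer(baseline_year),
         population_scale = population_scale,
         smoking_target = smoking_target,
         uptake_ages = as.integer(uptake_ages), gompertz = gompertz,
         diseases = diseases, rr_allcause_current = rr_allcause_current,
         rr_halflife = rr_halflife, noise_sd = noise_sd),
    class = "synthetic_config"
  )
}

#' @rdname synthetic_config
#' @export
default_disease_params <- function() {
  list(
    list(name = "lung_cancer_like", inc_max = 0.0035, onset = 40, peak = 72,
         duration = 3, excess_mortality = 0.25, rr_current = 10,
         female_factor = 0.7),
    list(name = "copd_like", inc_max = 0.006, onset = 35, peak = 70,
         duration = 8, excess_mortality = 0.03, rr_current = 6,
         female_factor = 0.7),
    list(name = "ihd_like", inc_max = 0.012, onset = 35, peak = 80,
         duration = 8, excess_mortality = 0.02, rr_current = 2,
         female_factor = 0.7)
  )
}

# Gamma-like unimodal age curve: 0 before onset, peaks at `peak` with value 1.
age_incidence_shape <- function(ages, onset, peak) {
  x <- pmax(ages - onset, 0) / (peak - onset)
  (x^3) * exp(3 * (1 - x))
}

# Adolescent uptake curve: 0 at the window start, saturating above it.
uptake_curve <- function(ages, lo) {
  u <- 1 - exp(-(pmax(ages - lo, 0) / 6)^2.5)
  u[ages < lo] <- 0
  u
}

#' Generate a synthetic input bundle
#'
#' Builds a complete, validated [smoking_bundle()] from a
#' [synthetic_config()]. The adult (18-65) current-smoker prevalence matches
#' the configured target to within a fraction of a percentage point by
#' construction; adolescent start rates reproduce the adolescent prevalence
#' curve exactly through the life-table identity; former-smoker relative
#' risks decay monotonically toward 1 across the time-since-quit classes; and
#' the disease burden is checked against total mortality so the additive
#' other-cause decomposition is feasible at every age, sex, and class.
#'
#' @param config A [synthetic_config()].
#' @return A validated [smoking_bundle()].
#' @export
generate_bundle <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  with_local_seed(config$seed, build_synthetic_bundle(config))
}

build_synthetic_bundle <- function(cf) {
  am <- cf$age_max
  ages <- ages_of(am)
  n_age <- am + 1L
  k <- cf$k_classes
  nc <- k + 2L
  noise <- function(n = 1) exp(stats::rnorm(n, 0, cf$noise_sd))

  # --- demography: smooth pyramid, flat through midlife, fading at old age
  pyramid <- 1 / (1 + exp((ages - 72) / 9))
  population <- blank_ast(am)
  population[, "male"] <- cf$population_scale * pyramid
  population[, "female"] <- cf$population_scale * pyramid *
    (1 + pmin(ages, 90) / 900) # slight female surplus at old age
  newborns <- matrix(rep(population[1, ], each = 120), ncol = 2,
                     dimnames = list(NULL, SEXES))

  # --- smoking-state prevalence
  lo <- cf$uptake_ages[1]
  hi <- cf$uptake_ages[2]
  up <- uptake_curve(ages, lo)
  decline <- 0.35 + 0.65 / (1 + exp((ages - 62) / 9))
  shape <- up * decline
  adult <- ages >= 18 & ages <= 65
  target <- cf$smoking_target * noise()
  smoking <- array(0, dim = c(n_age, 2L, nc),
                   dimnames = list(age = ages, sex = SEXES,
                                   class = smoking_classes(k)))
  if (cf$smoking_target == 0) {
    smoking[, , 1] <- 1
    start <- quit <- restart <- blank_ast(am)
  } else {
    sex_mult <- c(male = 1.05, female = 0.95)
    level <- target / mean(shape[adult]) # both sexes average to the target
    former_tot <- 0.42 * (1 - exp(-pmax(ages - hi, 0) / 22))
    # former mass shifts toward the open-ended class with age
    w_base <- exp(-(0:(k - 1)) / 6)
    for (s in 1:2) {
      current <- pmin(level * sex_mult[s] * shape, 0.95)
      former <- pmin(former_tot, 0.95 - current)
      never <- 1 - current - former
      smoking[, s, 1] <- never
      smoking[, s, 2] <- current
      for (a in seq_len(n_age)) {
        if (former[a] <= 0) next
        w <- w_base
        w[k] <- w[k] * (1 + max(0, ages[a] - 40) / 10)
        smoking[a, s, 3:nc] <- former[a] * w / sum(w)
      }
    }

    # --- transition rates
    start <- blank_ast(am)
    win <- ages >= lo & ages <= hi
    for (s in 1:2) {
      p_ns <- smoking[win, s, 1] # former is 0 inside the uptake window
      rates <- net_start_rates_from_prevalence(p_ns, ages = ages[win])
      start[as.character(ages[win][-sum(win)]), s] <- rates
      tail_ages <- ages > hi & ages <= hi + 10
      start[tail_ages, s] <- 0.004 * exp(-(ages[tail_ages] - hi) / 3) *
        noise(sum(tail_ages))
    }
    quit <- blank_ast(am)
    qa <- ages >= 16
    quit[qa, ] <- pmin(0.03 + 0.0004 * (ages[qa] - 16), 0.08) *
      rep(noise(2), each = sum(qa))
    restart <- blank_ast(am)
    restart[qa, ] <- 0.09 * exp(-(ages[qa] - 16) / 25) *
      rep(noise(2), each = sum(qa))
  }

  # --- all-cause mortality (Gompertz hazard + background, infant bump)
  gz <- cf$gompertz
  m_total <- blank_ast(am)
  for (s in 1:2) {
    fac <- if (s == 2) gz$female_factor else 1
    hazard <- fac * gz$modal_rate * exp(gz$slope * ages) + gz$background +
      0.002 * exp(-ages)
    m_total[, s] <- 1 - exp(-hazard)
  }

  # --- relative risk decay over time-since-quit classes
  decay <- 0.5^((0:(k - 1)) / cf$rr_halflife)
  rr_former_from <- function(rr_current) {
    1 + outer(rr_current - 1, decay)
  }
  smoke_on <- cf$smoking_target > 0
  rr_all_cur <- rep(if (smoke_on) cf$rr_allcause_current else 1, n_age)
  mortality <- list(m_total = m_total, rr_current = rr_all_cur,
                    rr_former = rr_former_from(rr_all_cur))

  # --- diseases
  diseases <- list()
  for (dp in cf$diseases) {
    lvl <- dp$inc_max * noise()
    shape_d <- age_incidence_shape(ages, dp$onset, dp$peak)
    incidence <- blank_ast(am)
    incidence[, "male"] <- lvl * shape_d
    incidence[, "female"] <- lvl * shape_d * dp$female_factor
    prevalence <- pmin(incidence * dp$duration, 0.95)
    excess <- blank_ast(am, dp$excess_mortality)
    excess[ages < dp$onset, ] <- 0
    rr_cur <- rep(if (smoke_on) dp$rr_current else 1, n_age)
    diseases[[dp$name]] <- disease_definition(
      dp$name, incidence, prevalence, excess, rr_cur,
      rr_former_from(rr_cur))
  }

  bundle <- smoking_bundle(
    demography = list(population = population, newborns = newborns),
    smoking = smoking,
    rates = list(start = start, quit = quit, restart = restart),
    diseases = diseases,
    mortality = mortality,
    age_max = am, k_classes = k, baseline_year = cf$baseline_year,
    validate = TRUE
  )
  # fail fast if the disease burden is infeasible under additive mortality
  compile_model(bundle)
  bundle
}

#' Small pinned fixture bundle
#'
#' A deliberately small synthetic bundle (ages 0-50, three time-since-quit
#' classes, two diseases, a few hundred thousand persons) whose content is
#' pinned by a fixed internal seed. Used for fast regression tests and as the
#' standard input for validating the compartmental engine against the
#' person-level microsimulation.
#'
#' @return A [smoking_bundle()].
#' @export
fixture_bundle <- function() {
  cf <- synthetic_config(
    seed = 42L, age_max = 50L, k_classes = 3L, population_scale = 4000,
    uptake_ages = c(10L, 20L),
    diseases = list(
      list(name = "lung_cancer_like", inc_max = 0.002, onset = 25, peak = 45,
           duration = 3, excess_mortality = 0.15, rr_current = 10,
           female_factor = 0.7),
      list(name = "ihd_like", inc_max = 0.004, onset = 25, peak = 48,
           duration = 8, excess_mortality = 0.02, rr_current = 2,
           female_factor = 0.7)
    )
  )
  generate_bundle(cf)
}
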