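#' Calibrate class-specific incidence against a population-average rate
#'
#' Disease registries report population-average incidence, while the model
#' needs incidence per smoking class such that exposed classes are a relative
#' -risk multiple of the never-smoker rate. Given the class shares of the
#' population and the relative risks (with `rr_never = 1`), the never-smoker
#' incidence is
#' `I_never = I_pop / sum(shares * rr)`, and `I_c = rr_c * I_never`, so that
#' the share-weighted mean of the class incidences reproduces `I_pop` exactly.
#'
#' @param i_pop Population-average incidence rate.
#' @param shares Numeric vector of class shares (must sum to 1).
#' @param rr Numeric vector of relative risks per class, same order as
#'   `shares`; the never-smoker entry must be 1.
#' @return Numeric vector of class-specific incidence rates.
#' @export
calibrate_class_specific_incidence <- function(i_pop, shares, rr) {
  stopifnot(length(shares) == length(rr), i_pop >= 0)
  if (abs(sum(shares) - 1) > 1e-9) stop("class shares must sum to 1",
                                        call. = FALSE)
  denom <- sum(shares * rr)
  if (denom == 0) {
    if (i_pop == 0) return(rep(0, length(rr)))
    stop("degenerate input: sum(shares * rr) = 0 with positive incidence",
         call. = FALSE)
  }
  rr * (i_pop / denom)
}

#' Other-cause mortality under the additive-mortality assumption
#'
#' Total mortality is decomposed into a disease-attributable part (the sum of
#' prevalence-weighted excess mortality over the modelled diseases) and an
#' other-cause remainder; the two components add.
#'
#' @param m_total All-cause mortality probability.
#' @param disease_mortality Disease-attributable mortality probability.
#' @param where Optional label (e.g. "age 80, male") used in error messages.
#' @return `m_total - disease_mortality`, which must be non-negative.
#' @export
derive_other_cause_mortality <- function(m_total, disease_mortality,
                                         where = NULL) {
  out <- m_total - disease_mortality
  if (any(out < 0)) {
    stop("disease-attributable mortality exceeds total mortality",
         if (!is.null(where)) paste0(" at ", where[which(out < 0)[1]]),
         ": inputs infeasible under additive mortality", call. = FALSE)
  }
  out
}

#' Class-specific total and other-cause mortality
#'
#' Smoking raises mortality both through the modelled diseases and through
#' causes outside the model. The latter channel is captured by the relative
#' risk on all-cause mortality: class-specific total mortality is set to
#' `M_c = rr_c * m_total / sum(shares * rr)`, which (i) reproduces the
#' observed all-cause mortality as its share-weighted mean and (ii) preserves
#' the all-cause relative risks between classes. The class's other-cause
#' component is then `M_c` minus its disease-attributable mortality.
#'
#' @param m_total All-cause mortality probability (scalar).
#' @param rr_allcause Relative risk on all-cause mortality per class
#'   (`rr_never = 1` first).
#' @param shares Class shares summing to 1.
#' @param disease_mortality_by_class Disease-attributable mortality per class.
#' @return List with `total` (vector `M_c`) and `other` (other-cause vector).
#' @export
derive_state_specific_mortality <- function(m_total, rr_allcause, shares,
                                            disease_mortality_by_class = 0) {
  stopifnot(length(shares) == length(rr_allcause))
  if (abs(sum(shares) - 1) > 1e-9) stop("class shares must sum to 1",
                                        call. = FALSE)
  denom <- sum(shares * rr_allcause)
  if (denom == 0) stop("degenerate input: sum(shares * rr) = 0",
                       call. = FALSE)
  total <- rr_allcause * (m_total / denom)
  other <- total - disease_mortality_by_class
  if (any(other < -1e-12)) {
    stop("class-specific disease mortality exceeds the class's total ",
         "mortality: inputs inconsistent with additive decomposition",
         call. = FALSE)
  }
  list(total = total, other = pmax(other, 0))
}

# ---- compiled model --------------------------------------------------------

#' Compile an input bundle into projection-ready rate tables
#'
#' Performs, once per run, the calibrations that turn population-average
#' inputs into class-specific rates: incidence per smoking class for each
#' disease, and other-cause mortality per class. Calibration uses the
#' *reference* exposure distribution (`calibration_smoking`), so that a
#' scenario's year-0 prevalence shock does not re-calibrate the underlying
#' class-specific rates away.
#'
#' @param bundle The bundle whose rates and tables are used for projection
#'   (possibly scenario-modified).
#' @param calibration_smoking Smoking-state array used for the calibration
#'   shares; defaults to `bundle$smoking` (appropriate for the reference run).
#' @return An opaque list consumed by [step_year()] and [run_projection()].
#' @export
compile_model <- function(bundle, calibration_smoking = bundle$smoking) {
  am <- bundle$age_max
  n_age <- am + 1L
  k <- bundle$k_classes
  nc <- k + 2L
  nd <- length(bundle$diseases)
  cls <- smoking_classes(k)
  dn <- unname(vapply(bundle$diseases, `[[`, "", "name"))

  inc <- array(0, dim = c(n_age, 2L, nc, max(nd, 1L)),
               dimnames = list(age = ages_of(am), sex = SEXES, class = cls,
                               disease = if (nd) dn else "none"))
  em <- array(0, dim = c(n_age, 2L, max(nd, 1L)),
              dimnames = list(age = ages_of(am), sex = SEXES,
                              disease = if (nd) dn else "none"))
  prev0 <- em

  for (j in seq_len(nd)) {
    d <- bundle$diseases[[j]]
    rrmat <- cbind(1, d$rr_current, d$rr_former) # [age, class]
    for (s in 1:2) {
      denom <- rowSums(calibration_smoking[, s, ] * rrmat)
      i_pop <- d$incidence[, s]
      bad <- denom == 0 & i_pop > 0
      if (any(bad)) {
        stop(sprintf(
          "degenerate incidence calibration for %s at age %d, sex %s",
          d$name, ages_of(am)[which(bad)[1]], SEXES[s]), call. = FALSE)
      }
      i_never <- ifelse(denom > 0, i_pop / denom, 0)
      inc[, s, , j] <- rrmat * i_never
    }
    em[, , j] <- d$excess_mortality
    prev0[, , j] <- d$prevalence
  }

  # all-cause mortality split by class, then other-cause remainder
  rrall <- cbind(1, bundle$mortality$rr_current, bundle$mortality$rr_former)
  oc <- array(0, dim = c(n_age, 2L, nc),
              dimnames = list(age = ages_of(am), sex = SEXES, class = cls))
  for (s in 1:2) {
    denom <- rowSums(calibration_smoking[, s, ] * rrall)
    if (any(denom == 0 & bundle$mortality$m_total[, s] > 0)) {
      stop("degenerate all-cause mortality calibration", call. = FALSE)
    }
    m_class <- rrall * ifelse(denom > 0,
                              bundle$mortality$m_total[, s] / denom, 0)
    # baseline disease prevalence is population-average across classes, so the
    # disease-attributable part is class-invariant at calibration time
    dm <- if (nd) rowSums(prev0[, s, , drop = FALSE] * em[, s, , drop = FALSE],
                          dims = 1) else rep(0, n_age)
    other <- m_class - dm
    if (any(other < -1e-12)) {
      i <- which(other < -1e-12, arr.ind = TRUE)[1, ]
      stop(sprintf(paste0(
        "disease mortality exceeds class-specific total mortality at age %d,",
        " sex %s, class %s: inputs infeasible"), ages_of(am)[i[1]], SEXES[s],
        cls[i[2]]), call. = FALSE)
    }
    oc[, s, ] <- pmax(other, 0)
  }

  list(age_max = am, k_classes = k, n_classes = nc, n_diseases = nd,
       disease_names = if (nd) dn else character(),
       inc = inc, em = em, oc = oc, prev0 = prev0,
       rates = bundle$rates,
       newborns = bundle$demography$newborns)
}

#' Baseline population state of a bundle
#'
#' Distributes the baseline population over smoking classes using the
#' bundle's smoking-state fractions, and assigns every class the
#' population-average baseline disease prevalence.
#'
#' @param bundle A [smoking_bundle()].
#' @return A `population_state`: list with `count` (`[age, sex, class]`) and
#'   `prev` (`[age, sex, class, disease]`).
#' @export
initial_state <- function(bundle) {
  am <- bundle$age_max
  nc <- bundle$k_classes + 2L
  nd <- length(bundle$diseases)
  cls <- smoking_classes(bundle$k_classes)
  dn <- unname(vapply(bundle$diseases, `[[`, "", "name"))
  count <- bundle$smoking *
    array(bundle$demography$population, dim = c(am + 1L, 2L, nc))
  dimnames(count) <- list(age = ages_of(am), sex = SEXES, class = cls)
  prev <- array(0, dim = c(am + 1L, 2L, nc, max(nd, 1L)),
                dimnames = list(age = ages_of(am), sex = SEXES, class = cls,
                                disease = if (nd) dn else "none"))
  for (j in seq_len(nd)) {
    prev[, , , j] <- array(bundle$diseases[[j]]$prevalence,
                           dim = c(am + 1L, 2L, nc))
  }
  structure(list(count = count, prev = prev), class = "population_state")
}

#' Advance the population by one year
#'
#' Applies the model's annual update in a fixed order: (1) smoking-state
#' transitions (never to current via start; current to `former_0` via quit;
#' former classes back to current via restart; surviving former smokers
#' advance one time-since-quit class, the last class being absorbing), (2)
#' disease incidence on the disease-free fraction of each class at the
#' calibrated class-specific rates, (3) mortality combining each disease's
#' excess mortality on the diseased fraction with class-specific other-cause
#' mortality, (4) ageing by one year, with newborns entering at age 0 as
#' disease-free never smokers and survivors of the top age exiting the model.
#' People who change smoking class carry their disease prevalence with them.
#'
#' @param state A `population_state` (see [initial_state()]).
#' @param model A compiled model from [compile_model()].
#' @param newborns Length-2 vector (male, female) entering age 0 next year.
#' @return List with the next `state`, a `deaths` matrix `[age, sex]` indexed
#'   by age at the start of the year, a `new_cases` array
#'   `[age, sex, class, disease]`, and `exits` (survivors leaving at the top
#'   age, by sex).
#' @export
step_year <- function(state, model, newborns = c(0, 0)) {
  n_age <- model$age_max + 1L
  nc <- model$n_classes
  nd <- model$n_diseases
  count <- state$count
  dis <- state$prev * array(count, dim = dim(state$prev)) # diseased counts

  start <- model$rates$start
  quit <- model$rates$quit
  restart <- model$rates$restart

  flow <- function(x) {
    # x: [age, sex, class] -> same shape after smoking transitions
    out <- array(0, dim = dim(x), dimnames = dimnames(x))
    nv <- x[, , 1]
    cur <- x[, , 2]
    fm_tot <- if (nc > 3) rowSums(x[, , 3:nc], dims = 2) else x[, , 3]
    out[, , 1] <- nv * (1 - start)
    out[, , 2] <- nv * start + cur * (1 - quit) + fm_tot * restart
    out[, , 3] <- cur * quit
    if (nc > 3) {
      for (j in 3:(nc - 1L)) {
        out[, , j + 1L] <- out[, , j + 1L] + x[, , j] * (1 - restart)
      }
    }
    out[, , nc] <- out[, , nc] + x[, , nc] * (1 - restart)
    out
  }

  count <- flow(count)
  for (j in seq_len(max(nd, 1L))) dis[, , , j] <- flow(dis[, , , j])
  prev <- dis / array(pmax(count, .Machine$double.xmin),
                      dim = dim(dis))
  prev[dis == 0] <- 0

  # disease incidence among the disease-free, per class
  new_cases <- array(0, dim = dim(prev), dimnames = dimnames(prev))
  for (j in seq_len(nd)) {
    p <- prev[, , , j]
    cases <- count * (1 - p) * model$inc[, , , j]
    new_cases[, , , j] <- cases
    prev[, , , j] <- p + (1 - p) * model$inc[, , , j]
  }

  # mortality: other-cause per class + excess mortality on the diseased
  rsum <- array(0, dim = dim(count))
  for (j in seq_len(nd)) {
    rsum <- rsum + prev[, , , j] *
      array(model$em[, , j], dim = dim(count))
  }
  q <- model$oc + rsum
  if (any(q > 1)) {
    warning("combined mortality probability exceeded 1 in some cells; ",
            "clamped", call. = FALSE)
    q <- pmin(q, 1)
  }
  deaths_cell <- count * q
  deaths <- rowSums(deaths_cell, dims = 2)
  survivors <- count - deaths_cell
  for (j in seq_len(nd)) {
    p <- prev[, , , j]
    emj <- array(model$em[, , j], dim = dim(count))
    q_dis <- q + emj * (1 - p) # death prob of the diseased (independence)
    surv_dis <- count * p * (1 - q_dis)
    prev[, , , j] <- ifelse(survivors > 0, surv_dis / survivors, 0)
  }

  # ageing; top-age survivors exit the (closed) model population
  exits <- rowSums(matrix(survivors[n_age, , ], nrow = 2L))
  names(exits) <- SEXES
  count_next <- array(0, dim = dim(count), dimnames = dimnames(count))
  prev_next <- array(0, dim = dim(prev), dimnames = dimnames(prev))
  count_next[2:n_age, , ] <- survivors[1:(n_age - 1L), , ]
  prev_next[2:n_age, , , ] <- prev[1:(n_age - 1L), , , ]
  count_next[1, , 1] <- newborns

  list(state = structure(list(count = count_next, prev = prev_next),
                         class = "population_state"),
       deaths = deaths, new_cases = new_cases, exits = exits)
}

#' Run a scenario projection
#'
#' Builds the scenario-modified bundle (see [build_scenario_bundle()]),
#' calibrates class-specific rates against the reference exposure
#' distribution, and iterates [step_year()] over the projection horizon. The
#' scenario only alters year-0 prevalence and/or transition rates; smoking
#' prevalence in later years is an outcome of the dynamics, never re-imposed.
#' The engine is fully deterministic (expected-value compartmental model).
#'
#' @param bundle The reference [smoking_bundle()].
#' @param scenario A [scenario_spec()]; default is the reference scenario.
#' @param horizon Number of projection years; defaults to
#'   `scenario$horizon_years`.
#' @return A `projection_result`: yearly states, deaths, incident cases, and
#'   top-age exits, plus the scenario and a bundle fingerprint.
#' @export
run_projection <- function(bundle, scenario = scenario_spec("reference"),
                           horizon = scenario$horizon_years) {
  stopifnot(inherits(bundle, "smoking_bundle"), horizon >= 0)
  scen_bundle <- build_scenario_bundle(bundle, scenario)
  model <- compile_model(scen_bundle, calibration_smoking = bundle$smoking)
  state <- initial_state(scen_bundle)

  n_age <- bundle$age_max + 1L
  years <- bundle$baseline_year + 0:horizon
  counts <- vector("list", horizon + 1L)
  prevs <- vector("list", horizon + 1L)
  counts[[1]] <- state$count
  prevs[[1]] <- state$prev
  deaths <- array(0, dim = c(horizon, n_age, 2L),
                  dimnames = list(year = if (horizon) years[1:horizon],
                                  age = ages_of(bundle$age_max), sex = SEXES))
  new_cases <- vector("list", horizon)
  exits <- matrix(0, nrow = horizon, ncol = 2L,
                  dimnames = list(if (horizon) years[1:horizon], SEXES))

  nb <- model$newborns
  for (t in seq_len(horizon)) {
    nb_t <- nb[min(t, nrow(nb)), ]
    stepped <- step_year(state, model, newborns = nb_t)
    state <- stepped$state
    counts[[t + 1L]] <- state$count
    prevs[[t + 1L]] <- state$prev
    deaths[t, , ] <- stepped$deaths
    new_cases[[t]] <- stepped$new_cases
    exits[t, ] <- stepped$exits
  }

  structure(
    list(years = years, counts = counts, prev = prevs, deaths = deaths,
         new_cases = new_cases, exits = exits, scenario = scenario,
         age_max = bundle$age_max, k_classes = bundle$k_classes,
         disease_names = unname(vapply(bundle$diseases, `[[`, "", "name")),
         baseline_year = bundle$baseline_year,
         bundle_checksum = bundle_checksum(bundle)),
    class = "projection_result"
  )
}

#' @export
print.projection_result <- function(x, ...) {
  cat("<projection_result>\n")
  cat("  scenario:", x$scenario$variant, "\n")
  cat("  years:", min(x$years), "-", max(x$years), "\n")
  cat("  population at baseline:",
      format(round(sum(x$counts[[1]])), big.mark = ","), "\n")
  invisible(x)
}

# Cheap content fingerprint identifying the bundle a result came from.
bundle_checksum <- function(b) {
  v <- c(b$age_max, b$k_classes, length(b$diseases),
         sum(b$demography$population),
         sum(b$smoking * seq_along(b$smoking)),
         sum(b$rates$start), sum(b$rates$quit), sum(b$rates$restart),
         sum(b$mortality$m_total))
  paste(format(v, digits = 15), collapse = ":")
}
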