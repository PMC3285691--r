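#' Person-level microsimulation oracle
#'
#' Simulates individual persons with per-year Bernoulli draws using exactly
#' the compartmental engine's event ordering (smoking transitions, then
#' disease incidence, then mortality, then ageing). It exists to validate
#' [step_year()]: as the number of simulated persons grows, occupancy and
#' death series converge to the engine's expected-value output. It is a test
#' oracle, not a production engine — the projection itself is deterministic.
#'
#' The cohort is closed: persons are sampled from the bundle's baseline joint
#' distribution of age, sex, smoking class, and disease status, and no
#' newborns enter (compare against an engine run with newborns zeroed).
#' Survivors of the top age exit, as in the engine.
#'
#' @param bundle A [smoking_bundle()].
#' @param scenario A [scenario_spec()]; rates and year-0 prevalence are
#'   modified exactly as in [run_projection()].
#' @param n_persons Number of simulated persons (keep moderate; cost is
#'   `O(n_persons * horizon)`).
#' @param seed Integer seed for all draws.
#' @param horizon Number of simulated years.
#' @return List with `class_counts` (matrix `[horizon + 1, classes]` of alive
#'   persons at the start of each year), `deaths` (per-year death counts),
#'   `exits` (per-year top-age exits), `n_persons`, and `scale` (bundle
#'   population per simulated person, for comparison against engine counts).
#' @export
microsim_oracle <- function(bundle, scenario = scenario_spec("reference"),
                            n_persons = 10000L, seed = 1L, horizon = 10L) {
  stopifnot(n_persons >= 1, n_persons <= 1e5, horizon >= 0)
  scen_bundle <- build_scenario_bundle(bundle, scenario)
  model <- compile_model(scen_bundle, calibration_smoking = bundle$smoking)
  n_age <- bundle$age_max + 1L
  nc <- model$n_classes
  nd <- model$n_diseases
  cls <- smoking_classes(bundle$k_classes)

  with_local_seed(seed, {
    # sample persons from the baseline joint (age, sex, class) distribution
    wt <- as.vector(initial_state(scen_bundle)$count)
    cell <- sample.int(length(wt), n_persons, replace = TRUE, prob = wt)
    dims <- c(n_age, 2L, nc)
    idx <- arrayInd(cell, dims)
    age <- idx[, 1] # 1-based: age in years is age - 1
    sex <- idx[, 2]
    class <- idx[, 3]
    has <- matrix(FALSE, n_persons, max(nd, 1L))
    for (j in seq_len(nd)) {
      p0 <- scen_bundle$diseases[[j]]$prevalence[cbind(age, sex)]
      has[, j] <- runif(n_persons) < p0
    }
    alive <- rep(TRUE, n_persons)

    class_counts <- matrix(0L, horizon + 1L, nc,
                           dimnames = list(NULL, cls))
    deaths <- integer(horizon)
    exits <- integer(horizon)
    tally <- function(t) {
      tab <- tabulate(class[alive], nbins = nc)
      class_counts[t, ] <<- tab
    }
    tally(1L)

    for (t in seq_len(horizon)) {
      a <- which(alive)
      if (length(a) == 0) break
      ai <- age[a]
      si <- sex[a]
      ci <- class[a]
      u <- runif(length(a))
      # smoking transitions (same one-pass rules as the engine's flow)
      new_ci <- ci
      nv <- ci == 1L
      cur <- ci == 2L
      fmr <- ci >= 3L
      sv <- model$rates$start[cbind(ai, si)]
      qv <- model$rates$quit[cbind(ai, si)]
      rv <- model$rates$restart[cbind(ai, si)]
      new_ci[nv & u < sv] <- 2L
      new_ci[cur & u < qv] <- 3L
      restart_draw <- fmr & u < rv
      new_ci[restart_draw] <- 2L
      advance <- fmr & !restart_draw
      new_ci[advance] <- pmin(ci[advance] + 1L, nc)
      ci <- new_ci
      # disease incidence among the disease-free
      for (j in seq_len(nd)) {
        free <- !has[a, j]
        pj <- model$inc[, , , j][cbind(ai, si, ci)]
        onset <- free & runif(length(a)) < pj
        has[a[onset], j] <- TRUE
      }
      # mortality: other-cause for the class + excess for each disease held
      p_die <- model$oc[cbind(ai, si, ci)]
      for (j in seq_len(nd)) {
        p_die <- p_die + has[a, j] * model$em[, , j][cbind(ai, si)]
      }
      die <- runif(length(a)) < p_die
      deaths[t] <- sum(die)
      # ageing; survivors of the top age exit the model population
      out <- !die & ai == n_age
      exits[t] <- sum(out)
      alive[a[die | out]] <- FALSE
      keep <- !(die | out)
      age[a[keep]] <- ai[keep] + 1L
      class[a] <- ci
      tally(t + 1L)
    }

    list(class_counts = class_counts, deaths = deaths, exits = exits,
         n_persons = n_persons,
         scale = sum(scen_bundle$demography$population) / n_persons)
  })
}
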