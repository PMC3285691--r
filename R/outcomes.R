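year_index <- function(result, year) {
  i <- match(year, result$years)
  if (is.na(i)) stop("year ", year, " is outside the projection (",
                     min(result$years), "-", max(result$years), ")",
                     call. = FALSE)
  i
}

#' Smoking prevalence series from a projection
#'
#' Collapses the time-since-quit strata so classes are reported as never /
#' current / former, either as one series per year (population aggregate,
#' optionally age-restricted) or as age profiles per year.
#'
#' @param result A `projection_result`.
#' @param by `"year"` for one value per class and year, or `"year_age"` for
#'   age profiles (sexes combined).
#' @param ages Optional inclusive age range `c(lo, hi)` to restrict to.
#' @param normalize If `TRUE` (default) report fractions of the living
#'   population; if `FALSE` report absolute counts. Note that class
#'   *fractions* of two scenarios can differ even when the class *counts* are
#'   identical, because scenarios change total survival (the denominator).
#' @return Tibble with columns `year`, (`age`,) `class`, `value`.
#' @export
smoking_prevalence_series <- function(result, by = c("year", "year_age"),
                                      ages = NULL, normalize = TRUE) {
  by <- match.arg(by)
  all_ages <- 0:result$age_max
  keep <- if (is.null(ages)) rep(TRUE, length(all_ages)) else
    all_ages >= ages[1] & all_ages <= ages[2]
  nc <- result$k_classes + 2L
  rows <- lapply(seq_along(result$years), function(i) {
    cnt <- result$counts[[i]][keep, , , drop = FALSE]
    never <- matrix(cnt[, , 1], ncol = 2)
    current <- matrix(cnt[, , 2], ncol = 2)
    former <- matrix(rowSums(cnt[, , 3:nc, drop = FALSE], dims = 2), ncol = 2)
    if (by == "year") {
      v <- c(never = sum(never), current = sum(current),
             former = sum(former))
      if (normalize) v <- v / sum(v)
      tibble::tibble(year = result$years[i], class = names(v),
                     value = unname(v))
    } else {
      n_a <- rowSums(never) # sexes combined
      c_a <- rowSums(current)
      f_a <- rowSums(former)
      tot <- n_a + c_a + f_a
      if (normalize) {
        n_a <- ifelse(tot > 0, n_a / tot, 0)
        c_a <- ifelse(tot > 0, c_a / tot, 0)
        f_a <- ifelse(tot > 0, f_a / tot, 0)
      }
      tibble::tibble(year = result$years[i],
                     age = rep(all_ages[keep], 3),
                     class = rep(c("never", "current", "former"),
                                 each = sum(keep)),
                     value = c(n_a, c_a, f_a))
    }
  })
  do.call(rbind, rows)
}

#' Point prevalence of one disease
#'
#' Number of prevalent cases of a disease at the start of a calendar year:
#' the sum over age, sex, and smoking class of population count times the
#' cell's disease-prevalence fraction.
#'
#' @param result A `projection_result`.
#' @param year Calendar year within the projection.
#' @param disease Disease name.
#' @return Case count (numeric scalar).
#' @export
disease_point_prevalence <- function(result, year, disease) {
  i <- year_index(result, year)
  j <- match(disease, result$disease_names)
  if (is.na(j)) stop("unknown disease: ", disease, call. = FALSE)
  sum(result$counts[[i]] * result$prev[[i]][, , , j])
}

# Fraction with at least one disease per (age, sex), independence product.
aloa_fraction <- function(result, i) {
  cnt <- result$counts[[i]]
  nd <- length(result$disease_names)
  free <- array(1, dim = dim(cnt))
  for (j in seq_len(nd)) free <- free * (1 - result$prev[[i]][, , , j])
  diseased <- cnt * (1 - free)
  pop <- rowSums(cnt, dims = 2)
  frac <- rowSums(diseased, dims = 2) / ifelse(pop > 0, pop, 1)
  frac[pop == 0] <- 0
  frac # [age, sex]
}

#' Persons with at least one modelled disease
#'
#' Counts persons having at least one of the bundle's diseases, assuming
#' independent co-occurrence within each (age, sex, smoking class) cell:
#' the cell fraction is `1 - prod_d(1 - prev_d)`.
#'
#' @inheritParams disease_point_prevalence
#' @return Case count (numeric scalar); 0 when the bundle has no diseases.
#' @export
at_least_one_disease <- function(result, year) {
  i <- year_index(result, year)
  if (length(result$disease_names) == 0) return(0)
  cnt <- result$counts[[i]]
  free <- array(1, dim = dim(cnt))
  for (j in seq_along(result$disease_names)) {
    free <- free * (1 - result$prev[[i]][, , , j])
  }
  sum(cnt * (1 - free))
}

#' Excess deaths of a scenario relative to the reference
#'
#' Per projection year, the difference in total deaths
#' `scenario - reference`; negative values are deaths averted by the
#' intervention. Both results must come from the same bundle and horizon.
#'
#' @param scenario_result,reference_result `projection_result`s of equal
#'   horizon over the same bundle.
#' @return Tibble with `year` (year the deaths occur in) and `excess_deaths`.
#' @export
excess_deaths_series <- function(scenario_result, reference_result) {
  if (!identical(scenario_result$years, reference_result$years)) {
    stop("results have mismatched projection horizons", call. = FALSE)
  }
  if (!identical(scenario_result$bundle_checksum,
                 reference_result$bundle_checksum)) {
    stop("results come from different input bundles", call. = FALSE)
  }
  h <- length(scenario_result$years) - 1L
  tibble::tibble(
    year = scenario_result$years[seq_len(h)],
    excess_deaths = unname(rowSums(scenario_result$deaths, dims = 1) -
                             rowSums(reference_result$deaths, dims = 1))
  )
}

#' Period life expectancy from age-specific mortality
#'
#' Standard period life table with the midpoint (half-year) person-year
#' convention: `l(0) = 1`, `l(a+1) = l(a) * (1 - q(a))`,
#' `L(a) = (l(a) + l(a+1)) / 2`, `e0 = sum(L(a) * w(a))`. The final age is
#' closed (`q` forced to 1), so with zero mortality `e0 = age_max + 0.5`.
#' With health weights `w(a)` (fraction free of disease at age `a`) this is
#' the Sullivan estimator of disease-free life expectancy.
#'
#' @param qx Vector of annual death probabilities by age, from age 0.
#' @param weights Optional person-year weights in `[0,1]` per age (default 1).
#' @return Life expectancy at age 0, in years.
#' @export
period_life_expectancy <- function(qx, weights = NULL) {
  stopifnot(all(qx >= 0), all(qx <= 1))
  n <- length(qx)
  qx[n] <- 1 # closed top age: everyone exits by the end of the last age
  l <- cumprod(c(1, 1 - qx))
  L <- (l[-(n + 1)] + l[-1]) / 2
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(length(weights) == n)
  sum(L * weights)
}

#' (Disease-free) life expectancy in a projection year
#'
#' Builds a period life table from the year's age-specific mortality
#' (deaths divided by start-of-year population, by sex). `mode = "total"`
#' returns ordinary life expectancy at birth; `mode = "disease_free"` weights
#' person-years by the fraction of the population free of all modelled
#' diseases at each age (Sullivan method). Disease-free life expectancy can
#' never exceed total life expectancy.
#'
#' @param result A `projection_result`.
#' @param year Calendar year; must be before the final projection year (the
#'   final year has no observed deaths).
#' @param sex `"male"` or `"female"`.
#' @param mode `"total"` or `"disease_free"`.
#' @return Life expectancy at birth, in years.
#' @export
life_expectancy <- function(result, year, sex = c("male", "female"),
                            mode = c("total", "disease_free")) {
  sex <- match.arg(sex)
  mode <- match.arg(mode)
  i <- year_index(result, year)
  if (i > dim(result$deaths)[1]) {
    stop("no deaths observed for year ", year,
         ": it is the final projection year", call. = FALSE)
  }
  s <- match(sex, SEXES)
  pop <- rowSums(result$counts[[i]][, s, , drop = FALSE], dims = 1)
  dth <- result$deaths[i, , s]
  zero <- pop <= 0
  if (any(zero)) {
    first0 <- which(zero)[1]
    if (first0 == 1) stop("no population at age 0 in year ", year,
                          call. = FALSE)
    warning("zero population at age ", first0 - 1L, " in year ", year,
            "; life table truncated", call. = FALSE)
    pop <- pop[seq_len(first0 - 1L)]
    dth <- dth[seq_len(first0 - 1L)]
  }
  qx <- pmin(dth / pop, 1)
  w <- NULL
  if (mode == "disease_free") {
    w <- (1 - aloa_fraction(result, i)[, s])[seq_along(qx)]
  }
  period_life_expectancy(qx, w)
}

#' Scenario-versus-reference comparison table
#'
#' For each requested year and outcome (each disease's point prevalence and,
#' with more than one disease, the "at least one disease" count), tabulates
#' the reference value, the scenario value, and the difference
#' `reference - scenario`, so positive differences are cases averted by the
#' intervention.
#'
#' @param reference_result,scenario_result `projection_result`s over the same
#'   bundle and horizon.
#' @param years Calendar years to tabulate.
#' @param outcomes Outcome names; defaults to all diseases plus
#'   `"at_least_one_disease"`.
#' @return Tibble with `year`, `outcome`, `reference`, `scenario`,
#'   `difference`.
#' @export
comparison_table <- function(reference_result, scenario_result, years,
                             outcomes = NULL) {
  if (is.null(outcomes)) {
    outcomes <- c(reference_result$disease_names,
                  if (length(reference_result$disease_names) > 1)
                    "at_least_one_disease")
  }
  grid <- expand.grid(year = years, outcome = outcomes,
                      stringsAsFactors = FALSE)
  val <- function(result, year, outcome) {
    if (outcome == "at_least_one_disease") at_least_one_disease(result, year)
    else disease_point_prevalence(result, year, outcome)
  }
  ref <- mapply(val, year = grid$year, outcome = grid$outcome,
                MoreArgs = list(result = reference_result))
  scn <- mapply(val, year = grid$year, outcome = grid$outcome,
                MoreArgs = list(result = scenario_result))
  tibble::tibble(year = grid$year, outcome = grid$outcome,
                 reference = ref, scenario = scn, difference = ref - scn)
}

#' Published headline values of the Dutch application
#'
#' The DYNAMO-HIA tool has been applied to the Netherlands with the national
#' input database (baseline smoking prevalence and transition probabilities,
#' relative risks, and nine-disease IPM tables). The headline values of that
#' application are tabulated here for context and documentation. They are
#' *not* reproducible with this package's synthetic input bundle: they
#' require the national database, which is external data and not shipped.
#' The shipped test suite checks the qualitative patterns (scenario ordering,
#' timing, sign structure) on synthetic inputs instead.
#'
#' @return Tibble with columns `quantity`, `scenario`, `year`, `sex`,
#'   `value`, `unit`, and `requires_external_data` (always `TRUE`).
#' @export
dutch_headline_values <- function() {
  t2 <- function(q, s, v) tibble::tibble(
    quantity = q, scenario = s, year = 2035, sex = NA_character_, value = v,
    unit = "cases averted vs reference")
  hle <- function(yr, s, m, f) tibble::tibble(
    quantity = "healthy life expectancy", scenario = s, year = yr,
    sex = c("male", "female"), value = c(m, f), unit = "years")
  out <- rbind(
    tibble::tibble(quantity = "all-cause deaths", scenario = "reference",
                   year = 2010, sex = NA_character_, value = 125650,
                   unit = "deaths"),
    tibble::tibble(
      quantity = paste(c("lung cancer", "COPD", "IHD", "at least one disease"),
                       "point prevalence"),
      scenario = "reference", year = 2010, sex = NA_character_,
      value = c(12863, 211798, 508596, 1483769), unit = "cases"),
    tibble::tibble(quantity = "current-smoker prevalence",
                   scenario = c("reference", "cessation (maximum)"),
                   year = 2035, sex = NA_character_, value = c(20, 14),
                   unit = "percent"),
    t2("lung cancer point prevalence", "cessation (maximum)", 2957),
    t2("lung cancer point prevalence", "initiation (maximum)", 3),
    t2("lung cancer point prevalence", "price policy (maximum)", 5044),
    t2("COPD point prevalence", "cessation (maximum)", 36087),
    t2("COPD point prevalence", "initiation (maximum)", 0),
    t2("COPD point prevalence", "price policy (maximum)", 66952),
    t2("IHD point prevalence", "cessation (maximum)", 23967),
    t2("IHD point prevalence", "initiation (maximum)", 94),
    t2("IHD point prevalence", "price policy (maximum)", 54071),
    hle(2010, "reference", 68.26, 71.45),
    hle(2035, "reference", 69.70, 71.90),
    hle(2035, "cessation (maximum)", 70.25, 72.30),
    hle(2035, "initiation (maximum)", 69.71, 71.91),
    hle(2035, "price policy (maximum)", 70.79, 72.73)
  )
  out$requires_external_data <- TRUE
  out
}
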