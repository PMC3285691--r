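#' Assemble a model input bundle
#'
#' An input bundle collects every age- and sex-specific table the projection
#' engine needs: baseline population counts and future newborn counts,
#' smoking-state prevalence, annual start/quit/restart probabilities,
#' per-disease incidence/prevalence/excess-mortality (IPM) tables with
#' incidence relative risks per smoking class, and all-cause mortality with
#' its own relative risks.
#'
#' All age-by-sex tables are numeric matrices with one row per single year of
#' age `0..age_max` (rownames `"0"`, `"1"`, ...) and columns `male`, `female`.
#' The smoking distribution is a 3-d array `[age, sex, class]` over the
#' classes of [smoking_classes()]. Relative risks vary by age (and class) but
#' not by sex, and `rr_never` is identically 1 (implicit; not stored).
#'
#' @param demography List with `population` (age-by-sex counts at the baseline
#'   year) and `newborns` (matrix of counts entering age 0, one row per
#'   projection year starting the year after baseline; recycled beyond its
#'   last row).
#' @param smoking Array `[age, sex, class]` of smoking-state fractions; each
#'   `(age, sex)` slice must sum to 1.
#' @param rates List of age-by-sex matrices `start`, `quit`, `restart` of
#'   annual transition probabilities. `start` applies to never smokers,
#'   `quit` to current smokers, `restart` to all former-smoker classes.
#' @param diseases Named list of disease definitions as returned by
#'   [disease_definition()].
#' @param mortality List with `m_total` (age-by-sex all-cause mortality
#'   probability per year), `rr_current` (all-cause relative risk of current
#'   smokers, by age), and `rr_former` (matrix `[age, k]` for the
#'   time-since-quit classes).
#' @param age_max Highest age modelled; the cohort is closed at this age
#'   (survivors exit at the end of the year).
#' @param k_classes Number of time-since-quit classes.
#' @param baseline_year Calendar year of the baseline population.
#' @param validate If `TRUE` (default), stop on any invariant violation.
#' @return An object of class `smoking_bundle`.
#' @seealso [validate_bundle()], [generate_bundle()], [load_bundle()]
#' @export
smoking_bundle <- function(demography, smoking, rates, diseases, mortality,
                           age_max = 105L, k_classes = 11L,
                           baseline_year = 2010L, validate = TRUE) {
  bundle <- structure(
    list(
      age_max = as.integer(age_max),
      k_classes = as.integer(k_classes),
      baseline_year = as.integer(baseline_year),
      demography = demography,
      smoking = smoking,
      rates = rates,
      diseases = diseases,
      mortality = mortality
    ),
    class = "smoking_bundle"
  )
  if (validate) assert_valid_bundle(bundle)
  bundle
}

#' Define one disease
#'
#' @param name Disease label.
#' @param incidence Age-by-sex matrix of population-average incidence
#'   (events per person-year among the disease-free).
#' @param prevalence Age-by-sex matrix of baseline prevalence fractions.
#' @param excess_mortality Age-by-sex matrix of excess death probability per
#'   year among the diseased (over and above other-cause mortality).
#' @param rr_current Incidence relative risk of current vs never smokers, one
#'   value per age.
#' @param rr_former Matrix `[age, k]` of incidence relative risks per
#'   time-since-quit class; expected to decay from `rr_current` toward 1.
#' @return A list of class `disease_definition`.
#' @export
disease_definition <- function(name, incidence, prevalence, excess_mortality,
                               rr_current, rr_former) {
  structure(
    list(name = name, incidence = incidence, prevalence = prevalence,
         excess_mortality = excess_mortality, rr_current = rr_current,
         rr_former = rr_former),
    class = "disease_definition"
  )
}

#' @export
print.smoking_bundle <- function(x, ...) {
  cat("<smoking_bundle>\n")
  cat("  baseline year:", x$baseline_year, "\n")
  cat("  ages: 0..", x$age_max, ", time-since-quit classes: ", x$k_classes,
      "\n", sep = "")
  cat("  population:", format(round(sum(x$demography$population)),
                              big.mark = ","), "\n")
  cat("  diseases:", paste(vapply(x$diseases, `[[`, "", "name"),
                           collapse = ", "), "\n")
  invisible(x)
}

# ---- validation ------------------------------------------------------------

violation <- function(severity, table, message) {
  tibble::tibble(severity = severity, table = table, message = message)
}

check_ast <- function(m, table, age_max, kind = c("rate", "count", "rr")) {
  kind <- match.arg(kind)
  out <- violation(character(), character(), character())
  if (!is.matrix(m) || nrow(m) != age_max + 1L || ncol(m) != 2L) {
    return(violation("error", table, sprintf(
      "expected a %d x 2 age-by-sex matrix", age_max + 1L)))
  }
  if (any(!is.finite(m))) {
    out <- rbind(out, violation("error", table, "non-finite values"))
    return(out)
  }
  bad <- switch(kind,
    rate  = which(m < 0 | m > 1, arr.ind = TRUE),
    count = which(m < 0, arr.ind = TRUE),
    rr    = which(m < 0, arr.ind = TRUE)
  )
  if (nrow(bad) > 0) {
    i <- bad[1, ]
    out <- rbind(out, violation("error", table, sprintf(
      "%s out of range at age %s, sex %s (value %g)",
      if (kind == "rate") "rate out of [0,1]" else "negative value",
      rownames(m)[i[1]], colnames(m)[i[2]], m[i[1], i[2]])))
  }
  out
}

#' Validate an input bundle
#'
#' Checks every structural invariant of the bundle: table shapes, finite
#' values, rates within `[0,1]`, counts non-negative, smoking-state fractions
#' summing to one at every age and sex, and relative risks non-negative.
#' Non-monotone decay of former-smoker relative risks across time-since-quit
#' classes is reported as a warning, not an error (real data may be noisy).
#'
#' @param bundle A [smoking_bundle()].
#' @return A tibble with columns `severity` (`"error"` or `"warning"`),
#'   `table`, and `message`; zero rows when the bundle is fully valid.
#' @export
validate_bundle <- function(bundle) {
  stopifnot(inherits(bundle, "smoking_bundle"))
  am <- bundle$age_max
  k <- bundle$k_classes
  n_age <- am + 1L
  rep0 <- violation(character(), character(), character())
  out <- rep0

  out <- rbind(out, check_ast(bundle$demography$population, "population", am,
                              "count"))
  nb <- bundle$demography$newborns
  if (!is.matrix(nb) || ncol(nb) != 2L) {
    out <- rbind(out, violation("error", "newborns",
                                "expected a year-by-sex matrix"))
  } else if (any(!is.finite(nb)) || any(nb < 0)) {
    out <- rbind(out, violation("error", "newborns",
                                "negative or non-finite newborn count"))
  }

  sm <- bundle$smoking
  cls <- smoking_classes(k)
  if (!is.array(sm) || !identical(dim(sm), c(n_age, 2L, length(cls)))) {
    out <- rbind(out, violation("error", "smoking", sprintf(
      "expected an array [%d ages x 2 sexes x %d classes]", n_age,
      length(cls))))
  } else {
    if (any(!is.finite(sm)) || any(sm < -1e-12) || any(sm > 1 + 1e-12)) {
      out <- rbind(out, violation("error", "smoking",
                                  "fraction outside [0,1]"))
    }
    tot <- apply(sm, c(1, 2), sum)
    bad <- which(abs(tot - 1) > 1e-9, arr.ind = TRUE)
    if (nrow(bad) > 0) {
      i <- bad[1, ]
      out <- rbind(out, violation("error", "smoking", sprintf(
        "state fractions sum to %.6f (not 1) at age %s, sex %s",
        tot[i[1], i[2]], ages_of(am)[i[1]], SEXES[i[2]])))
    }
  }

  for (nm in c("start", "quit", "restart")) {
    out <- rbind(out, check_ast(bundle$rates[[nm]], nm, am, "rate"))
  }

  for (d in bundle$diseases) {
    tb <- function(x) paste0(d$name, ".", x)
    out <- rbind(out, check_ast(d$incidence, tb("incidence"), am, "count"))
    out <- rbind(out, check_ast(d$prevalence, tb("prevalence"), am, "rate"))
    out <- rbind(out, check_ast(d$excess_mortality, tb("excess_mortality"),
                                am, "rate"))
    if (length(d$rr_current) != n_age || any(d$rr_current < 0)) {
      out <- rbind(out, violation("error", tb("rr_current"),
                                  "expected non-negative RR per age"))
    }
    if (!is.matrix(d$rr_former) || nrow(d$rr_former) != n_age ||
        ncol(d$rr_former) != k || any(d$rr_former < 0)) {
      out <- rbind(out, violation("error", tb("rr_former"), sprintf(
        "expected a non-negative %d x %d RR matrix", n_age, k)))
    } else if (length(d$rr_current) == n_age) {
      # soft check: RRs should lie between 1 and rr_current and decay with k
      lo <- pmin(1, d$rr_current) - 1e-9
      hi <- pmax(1, d$rr_current) + 1e-9
      outside <- d$rr_former < lo | d$rr_former > hi
      nonmono <- matrixStats_rowNonMonotone(d$rr_former, d$rr_current)
      if (any(outside) || any(nonmono)) {
        out <- rbind(out, violation("warning", tb("rr_former"),
          "former-smoker RRs do not decay monotonically from rr_current toward 1"))
      }
    }
  }

  out <- rbind(out, check_ast(bundle$mortality$m_total, "m_total", am, "rate"))
  if (length(bundle$mortality$rr_current) != n_age ||
      any(bundle$mortality$rr_current < 0)) {
    out <- rbind(out, violation("error", "mortality.rr_current",
                                "expected non-negative RR per age"))
  }
  if (!is.matrix(bundle$mortality$rr_former) ||
      nrow(bundle$mortality$rr_former) != n_age ||
      ncol(bundle$mortality$rr_former) != k ||
      any(bundle$mortality$rr_former < 0)) {
    out <- rbind(out, violation("error", "mortality.rr_former", sprintf(
      "expected a non-negative %d x %d RR matrix", n_age, k)))
  }
  out
}

# TRUE per age where rr_former is not non-increasing in k (given rr >= 1).
matrixStats_rowNonMonotone <- function(rrf, rrc) {
  if (ncol(rrf) < 2) return(rep(FALSE, nrow(rrf)))
  d <- rrf[, -1, drop = FALSE] - rrf[, -ncol(rrf), drop = FALSE]
  # direction of decay depends on whether the disease is harmful (rr > 1)
  up <- rrc >= 1
  apply(d > 1e-9, 1, any) & up | apply(d < -1e-9, 1, any) & !up
}

assert_valid_bundle <- function(bundle) {
  rep <- validate_bundle(bundle)
  errs <- rep[rep$severity == "error", , drop = FALSE]
  if (nrow(errs) > 0) {
    stop("invalid input bundle:\n", paste0(
      "  [", errs$table, "] ", errs$message, collapse = "\n"), call. = FALSE)
  }
  for (w in which(rep$severity == "warning")) {
    warning("[", rep$table[w], "] ", rep$message[w], call. = FALSE)
  }
  invisible(bundle)
}
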