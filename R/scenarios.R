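#' Specify an intervention scenario
#'
#' A scenario is a declarative description of how an intervention modifies the
#' reference (business-as-usual) input bundle: a cessation intervention
#' multiplies the odds of quitting, an initiation intervention reduces
#' adolescent start rates, and a population-wide price policy shifts year-0
#' smoking prevalence via price elasticities and rescales (re)start rates.
#' `reach` is the fraction of the target population actually exposed to the
#' intervention; effects mix linearly between the untreated and fully treated
#' rates, so reach 0 reproduces the reference scenario exactly.
#'
#' @param variant One of `"reference"`, `"cessation"`, `"initiation"`,
#'   `"price_policy"`.
#' @param quit_or Odds ratio applied to annual quit probabilities (cessation).
#' @param start_reduction Proportional reduction of start rates (initiation).
#' @param price_increase Proportional price increase, e.g. `0.95` for +95%
#'   (price policy).
#' @param elasticity_youth,elasticity_adult Price elasticities of smoking
#'   prevalence for persons up to `youth_max_age` and above it; youths are
#'   more price-responsive.
#' @param youth_max_age Last age treated with the youth elasticity.
#' @param restart_multiplier Multiplier applied to restart rates under the
#'   price policy, or `"derived"` to reduce restarting by the same proportion
#'   as the youth start rates (`1 - reduction`).
#' @param reach Fraction of the target population reached, in `[0,1]`.
#' @param target_ages Inclusive integer age range targeted; defaults to ages
#'   18 and over for cessation, 10-18 for initiation, everyone for the price
#'   policy.
#' @param horizon_years Default projection horizon for [run_projection()].
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(variant = c("reference", "cessation", "initiation",
                                      "price_policy"),
                          quit_or = NULL, start_reduction = NULL,
                          price_increase = NULL,
                          elasticity_youth = -0.7, elasticity_adult = -0.4,
                          youth_max_age = 20L, restart_multiplier = "derived",
                          reach = 1, target_ages = NULL,
                          horizon_years = 25L) {
  variant <- match.arg(variant)
  stopifnot(reach >= 0, reach <= 1)
  if (variant == "cessation") {
    if (is.null(quit_or) || quit_or <= 0) stop("cessation needs quit_or > 0",
                                               call. = FALSE)
    if (is.null(target_ages)) target_ages <- c(18L, Inf)
  }
  if (variant == "initiation") {
    if (is.null(start_reduction) || start_reduction < 0 ||
        start_reduction > 1) {
      stop("initiation needs start_reduction in [0,1]", call. = FALSE)
    }
    if (is.null(target_ages)) target_ages <- c(10L, 18L)
  }
  if (variant == "price_policy") {
    if (is.null(price_increase) || price_increase < 0) {
      stop("price policy needs price_increase >= 0", call. = FALSE)
    }
    for (e in c(elasticity_youth, elasticity_adult)) {
      if (abs(e) * price_increase > 1) {
        stop("elasticity x price increase implies a reduction > 100%",
             call. = FALSE)
      }
    }
    if (!identical(restart_multiplier, "derived")) {
      stopifnot(is.numeric(restart_multiplier), restart_multiplier >= 0,
                restart_multiplier <= 1)
    }
    if (is.null(target_ages)) target_ages <- c(0L, Inf)
  }
  structure(
    list(variant = variant, quit_or = quit_or,
         start_reduction = start_reduction, price_increase = price_increase,
         elasticity_youth = elasticity_youth,
         elasticity_adult = elasticity_adult,
         youth_max_age = as.integer(youth_max_age),
         restart_multiplier = restart_multiplier, reach = reach,
         target_ages = target_ages, horizon_years = as.integer(horizon_years)),
    class = "scenario_spec"
  )
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat("<scenario_spec>", x$variant, "\n")
  eff <- switch(x$variant,
    reference = "business as usual",
    cessation = sprintf("quit odds ratio %.2f", x$quit_or),
    initiation = sprintf("start-rate reduction %.0f%%",
                         100 * x$start_reduction),
    price_policy = sprintf(
      "price +%.0f%%, elasticities %.1f (<=%d) / %.1f, restart x %s",
      100 * x$price_increase, x$elasticity_youth, x$youth_max_age,
      x$elasticity_adult, format(x$restart_multiplier)))
  cat(" ", eff, "\n")
  cat("  reach:", sprintf("%.0f%%", 100 * x$reach),
      " target ages:", paste(x$target_ages, collapse = "-"), "\n")
  invisible(x)
}

in_target <- function(ages, target) ages >= target[1] & ages <= target[2]

#' Apply a cessation odds ratio to quit rates
#'
#' Transforms annual quit probabilities on the odds scale:
#' `q' = OR * q/(1-q) / (1 + OR * q/(1-q))`, which approximately doubles
#' small quit rates for `OR = 2`. With partial reach, the population mixes:
#' `reach * q' + (1 - reach) * q`.
#'
#' @param quit Age-by-sex matrix of annual quit probabilities in `[0,1)`.
#' @param quit_or Odds ratio (> 0).
#' @param reach Fraction of smokers reached.
#' @param target_ages Length-2 inclusive age range; rates outside it are
#'   untouched.
#' @return Modified quit-rate matrix.
#' @export
transform_quit_rates_or <- function(quit, quit_or, reach = 1,
                                    target_ages = c(18, Inf)) {
  stopifnot(quit_or > 0)
  if (any(quit == 1)) stop("quit rate of 1 has undefined odds", call. = FALSE)
  odds <- quit / (1 - quit)
  q_new <- (quit_or * odds) / (1 + quit_or * odds)
  mixed <- reach * q_new + (1 - reach) * quit
  sel <- in_target(as.integer(rownames(quit)), target_ages)
  out <- quit
  out[sel, ] <- mixed[sel, ]
  out
}

#' Apply a proportional reduction to start rates
#'
#' `s' = (1 - reach * start_reduction) * s` within the target ages (an
#' in-school intervention reduces initiation among those it reaches).
#'
#' @param start Age-by-sex matrix of annual start probabilities.
#' @param start_reduction Proportional reduction in `[0,1]`.
#' @inheritParams transform_quit_rates_or
#' @return Modified start-rate matrix.
#' @export
transform_start_rates <- function(start, start_reduction, reach = 1,
                                  target_ages = c(10, 18)) {
  stopifnot(start_reduction >= 0, start_reduction <= 1)
  sel <- in_target(as.integer(rownames(start)), target_ages)
  out <- start
  out[sel, ] <- (1 - reach * start_reduction) * start[sel, ]
  out
}

#' Prevalence reduction implied by a price increase
#'
#' The price elasticity of smoking prevalence measures the proportional
#' reduction in prevalence per proportional price increase; a 95% price
#' increase with elasticity -0.7 gives a 66.5% reduction.
#'
#' @param price_increase Proportional price increase (e.g. `0.95`).
#' @param elasticity Price elasticity of smoking prevalence (negative).
#' @return Reduction fraction `|elasticity| * price_increase`, in `[0,1]`.
#' @export
prevalence_reduction_from_price <- function(price_increase, elasticity) {
  stopifnot(price_increase >= 0)
  r <- abs(elasticity) * price_increase
  if (r > 1) stop("implied prevalence reduction exceeds 100%", call. = FALSE)
  r
}

#' Apply a population-wide price policy to a bundle
#'
#' Adults (above `youth_max_age`) respond by quitting immediately: their
#' current-smoker prevalence is scaled down by the adult reduction and the
#' removed mass enters the `former_0` class at year 0; their quit and start
#' rates are untouched. Youths respond by not starting: their current-smoker
#' prevalence is scaled down by the (larger) youth reduction with the removed
#' mass added to never smokers, and adolescent start rates are re-derived from
#' the scaled non-smoker curve via the life-table inverse
#' ([start_rates_for_target_prevalence()]) so that future cohorts hold the
#' post-intervention prevalence. Restart rates are multiplied by
#' `restart_multiplier` at all ages (`"derived"` uses `1 - youth reduction`,
#' i.e. the same proportional cut as the start rates). All modified rates are
#' held constant over the projection.
#'
#' @param bundle A [smoking_bundle()].
#' @param spec A price-policy [scenario_spec()].
#' @param uptake_ages Age range of the adolescent uptake window over which
#'   start rates are re-derived; defaults to 10 up to `spec$youth_max_age`.
#' @return The modified bundle.
#' @export
apply_price_policy <- function(bundle, spec,
                               uptake_ages = c(10L, spec$youth_max_age)) {
  stopifnot(spec$variant == "price_policy")
  r_youth <- spec$reach *
    prevalence_reduction_from_price(spec$price_increase,
                                    spec$elasticity_youth)
  r_adult <- spec$reach *
    prevalence_reduction_from_price(spec$price_increase,
                                    spec$elasticity_adult)
  if (r_youth == 0 && r_adult == 0) return(bundle)

  ages <- ages_of(bundle$age_max)
  youth <- ages <= spec$youth_max_age
  adult <- !youth
  sm <- bundle$smoking

  # youths: the removed smokers never start; mass moves to the never class
  removed_y <- sm[youth, , 2] * r_youth
  sm[youth, , 2] <- sm[youth, , 2] - removed_y
  sm[youth, , 1] <- sm[youth, , 1] + removed_y
  # adults: the removed smokers quit at once; mass moves to former_0
  removed_a <- sm[adult, , 2] * r_adult
  sm[adult, , 2] <- sm[adult, , 2] - removed_a
  sm[adult, , 3] <- sm[adult, , 3] + removed_a
  bundle$smoking <- sm

  # re-derive adolescent start rates from the scaled non-smoker curve so that
  # entering cohorts keep the post-intervention adolescent prevalence
  win <- ages >= uptake_ages[1] & ages <= uptake_ages[2]
  win_ages <- ages[win]
  start <- bundle$rates$start
  for (s in 1:2) {
    current_new <- sm[win, s, 2]
    p_ns <- 1 - current_new
    rates <- start_rates_for_target_prevalence(p_ns, ages = win_ages)
    start[as.character(win_ages[-length(win_ages)]), s] <- rates
  }
  bundle$rates$start <- start

  mult <- if (identical(spec$restart_multiplier, "derived")) 1 - r_youth else
    spec$restart_multiplier
  bundle$rates$restart <- bundle$rates$restart * mult
  bundle
}

#' Build the scenario-modified input bundle
#'
#' Dispatches on the scenario variant: the reference scenario returns the
#' bundle untouched; a cessation scenario modifies only quit rates; an
#' initiation scenario modifies only start rates; a price policy modifies
#' year-0 smoking prevalence plus start and restart rates.
#'
#' @param bundle A [smoking_bundle()].
#' @param scenario A [scenario_spec()].
#' @return The (possibly modified) bundle.
#' @export
build_scenario_bundle <- function(bundle, scenario) {
  stopifnot(inherits(bundle, "smoking_bundle"),
            inherits(scenario, "scenario_spec"))
  switch(scenario$variant,
    reference = bundle,
    cessation = {
      bundle$rates$quit <- transform_quit_rates_or(
        bundle$rates$quit, scenario$quit_or, scenario$reach,
        scenario$target_ages)
      bundle
    },
    initiation = {
      bundle$rates$start <- transform_start_rates(
        bundle$rates$start, scenario$start_reduction, scenario$reach,
        scenario$target_ages)
      bundle
    },
    price_policy = apply_price_policy(bundle, scenario),
    stop("unknown scenario variant: ", scenario$variant, call. = FALSE)
  )
}

#' Shipped scenario presets
#'
#' Six ready-made scenario specifications covering the three intervention
#' types in a maximum version (idealised effect and 100% reach) and a
#' realistic version (literature-informed effect and reach):
#'
#' * cessation: quit odds ratio 2.0 for adults 18+, reach 100% (maximum) or
#'   20% (realistic: 40% of smokers want to quit times 50% of those are
#'   reached);
#' * initiation: start-rate reduction of 50% (maximum) or 20% (realistic) at
#'   school ages 10-18, reach 100% or 50%;
#' * price policy: price increase of 95% (maximum; roughly the gap to the
#'   highest EU price level) or 20% (realistic), elasticities -0.7 up to age
#'   20 and -0.4 above, restart rates cut to 30% (maximum) or 80% (realistic)
#'   of reference, reach 100% in both.
#'
#' @param type `"cessation"`, `"initiation"`, or `"price_policy"`.
#' @param version `"maximum"` or `"realistic"`.
#' @param horizon_years Projection horizon stored in the spec.
#' @return A [scenario_spec()].
#' @export
scenario_preset <- function(type = c("cessation", "initiation",
                                     "price_policy"),
                            version = c("maximum", "realistic"),
                            horizon_years = 25L) {
  type <- match.arg(type)
  version <- match.arg(version)
  mx <- version == "maximum"
  switch(type,
    cessation = scenario_spec("cessation", quit_or = 2,
                              reach = if (mx) 1 else 0.4 * 0.5,
                              target_ages = c(18L, Inf),
                              horizon_years = horizon_years),
    initiation = scenario_spec("initiation",
                               start_reduction = if (mx) 0.5 else 0.2,
                               reach = if (mx) 1 else 0.5,
                               target_ages = c(10L, 18L),
                               horizon_years = horizon_years),
    price_policy = scenario_spec("price_policy",
                                 price_increase = if (mx) 0.95 else 0.20,
                                 restart_multiplier = if (mx) 0.30 else 0.80,
                                 reach = 1,
                                 horizon_years = horizon_years)
  )
}
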