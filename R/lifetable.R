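#' Net smoking initiation rates from a non-smoker prevalence curve
#'
#' Adolescent survey data typically distinguish only smokers from non-smokers,
#' so gross start and quit flows cannot be separated at those ages. The model
#' therefore uses "net" initiation rates: the non-smoker prevalence curve is
#' read as a standard life table of a cohort of non-smokers whose membership
#' shrinks only because people take up smoking. If 100 adolescents start and 4
#' quit in a year, the net uptake is 96; flows back into the non-smoking state
#' are not modelled at these ages.
#'
#' With non-smoker prevalence `p_ns(a)` at adjacent ages, the net annual start
#' probability is `s(a) = (p_ns(a) - p_ns(a+1)) / p_ns(a)`, so that a cohort
#' simulated forward with `l(a+1) = l(a) * (1 - s(a))` reproduces the curve
#' exactly. Because only ratios of adjacent values enter, the rates are
#' invariant under uniform rescaling of the curve.
#'
#' @param p_ns Numeric vector of non-smoker prevalence over a contiguous age
#'   range, named by age (or use `ages`).
#' @param ages Integer ages corresponding to `p_ns`; defaults to its names.
#' @return Named numeric vector of net start rates for each age except the
#'   last (one rate per adjacent pair).
#' @details Sampling noise in real data can make `p_ns` locally increasing,
#'   which would imply a negative net rate; such rates are clamped to 0 with a
#'   warning, since the cohort model admits no flow back into non-smoking.
#' @export
net_start_rates_from_prevalence <- function(p_ns, ages = NULL) {
  if (is.null(ages)) ages <- as.integer(names(p_ns))
  stopifnot(length(p_ns) >= 2, length(ages) == length(p_ns),
            !anyNA(ages), all(diff(ages) == 1L))
  if (any(!is.finite(p_ns)) || any(p_ns < 0) || any(p_ns > 1)) {
    stop("non-smoker prevalence must be in [0,1]", call. = FALSE)
  }
  head_p <- p_ns[-length(p_ns)]
  if (any(head_p == 0)) {
    stop("non-smoker prevalence is 0 at age ",
         ages[which(head_p == 0)[1]],
         " but a successor age exists: net start rate undefined",
         call. = FALSE)
  }
  s <- (head_p - p_ns[-1]) / head_p
  if (any(s < 0)) {
    warning("non-smoker prevalence increases between ages ",
            paste(ages[which(s < 0)], collapse = ", "),
            " and successors; clamping implied negative start rates to 0",
            call. = FALSE)
    s <- pmax(s, 0)
  }
  names(s) <- ages[-length(ages)]
  s
}

#' Start rates consistent with a target post-intervention prevalence
#'
#' Inverse use of the non-smoker life table: given a target adolescent
#' non-smoker prevalence curve (for instance the business-as-usual curve with
#' smoker prevalence scaled down by a price-elasticity effect), return the net
#' start rates under which newly entering cohorts hold adolescent smoker
#' prevalence at the target level. The algebra is identical to
#' [net_start_rates_from_prevalence()]; the distinct entry point marks the
#' distinct role (the curve is a target, not an observation).
#'
#' @inheritParams net_start_rates_from_prevalence
#' @return Named numeric vector of net start rates.
#' @export
start_rates_for_target_prevalence <- function(p_ns, ages = NULL) {
  net_start_rates_from_prevalence(p_ns, ages)
}

#' Forward-simulate a non-smoker cohort
#'
#' Runs the life table forward: `l(a0) = p0`, `l(a+1) = l(a) * (1 - s(a))`.
#' Used to verify that estimated net start rates reproduce an observed or
#' target prevalence curve.
#'
#' @param p0 Non-smoker prevalence at the first age.
#' @param start_rates Named numeric vector of net start rates (names = ages).
#' @return Numeric vector of non-smoker prevalence, one element longer than
#'   `start_rates`, named by age.
#' @export
cohort_nonsmoker_curve <- function(p0, start_rates) {
  l <- cumprod(c(p0, 1 - start_rates))
  a0 <- as.integer(names(start_rates)[1])
  names(l) <- seq(a0, by = 1L, length.out = length(l))
  l
}
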