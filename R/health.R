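# Simplified diet -> BMI -> disease -> HALY chain: a proportional multistate
# lifetable with annual cycles. Each disease runs in parallel (incidence,
# case fatality, remission acting on prevalence); an intervention scales
# incidence by (1 - PIF) after an optional lag, and the resulting prevalence
# differences perturb all-cause mortality (via case fatality) and morbidity
# (via disability weights) relative to business as usual. HALYs are
# morbidity-weighted life years, optionally discounted.

# rates may be a single constant or a data.frame(age, sex, rate) step
# function (age = lower bound of band, carried forward)
rate_fun <- function(x, what = "rate") {
  if (is.numeric(x) && length(x) == 1L) {
    if (x < 0) stop(what, " has negative rates")
    v <- x
    return(function(age, sex) v)
  }
  x <- as.data.frame(x)
  req <- c("age", "sex", "rate")
  if (!all(req %in% names(x)))
    stop(what, " table needs columns age, sex, rate")
  if (any(x$rate < 0)) stop(what, " has negative rates")
  x <- x[order(x$age), ]
  parts <- split(x, x$sex)
  function(age, sex) {
    tb <- parts[[sex]]
    if (is.null(tb)) stop("no ", what, " rates for sex '", sex, "'")
    tb$rate[findInterval(age, tb$age, rightmost.closed = FALSE)]
  }
}

#' Disease specification for the multistate lifetable
#'
#' Rates are annual per person-year and may be a scalar (constant over age
#' and sex) or a `data.frame(age, sex, rate)` giving the rate from each
#' starting age (step function).
#'
#' @param name disease label.
#' @param incidence,case_fatality,remission annual transition rates.
#' @param disability_weight dimensionless in [0, 1]; applied to prevalence
#'   to form the disease's morbidity contribution.
#' @param lag_years years before a PIF acts on incidence (hard step by
#'   default; `phase_in = TRUE` ramps the PIF linearly over the lag).
#' @param initial_prevalence prevalence at baseline, in [0, 1].
#' @param phase_in logical; linear phase-in of the PIF over the lag.
#' @return object of class `disease_spec`.
#' @export
disease_spec <- function(name, incidence, case_fatality, remission = 0,
                         disability_weight = 0.1, lag_years = 0,
                         initial_prevalence = 0, phase_in = FALSE) {
  if (disability_weight < 0 || disability_weight > 1)
    stop("disability_weight must be in [0, 1]")
  if (initial_prevalence < 0 || initial_prevalence > 1)
    stop("initial_prevalence must be in [0, 1]")
  if (lag_years < 0) stop("lag_years must be >= 0")
  structure(list(name = name,
                 incidence = rate_fun(incidence, "incidence"),
                 case_fatality = rate_fun(case_fatality, "case_fatality"),
                 remission = rate_fun(remission, "remission"),
                 disability_weight = disability_weight,
                 lag_years = lag_years,
                 initial_prevalence = initial_prevalence,
                 phase_in = phase_in),
            class = "disease_spec")
}

#' Population lifetable inputs
#'
#' @param cohorts `data.frame(age, sex, count)` of people alive at baseline.
#' @param mortality all-cause annual mortality: scalar or
#'   `data.frame(age, sex, rate)` with rates in [0, 1].
#' @param pyld prevalent years-lived-with-disability rate (morbidity per
#'   person-year, in [0, 1]): scalar or rate table.
#' @param discount_rate annual discount rate applied to HALYs (0 or 0.03
#'   typically).
#' @param max_age age at which rates stop being advanced (cohorts are
#'   simulated up to the horizon regardless).
#' @return object of class `population_lifetable`.
#' @export
population_lifetable <- function(cohorts, mortality, pyld = 0,
                                 discount_rate = 0, max_age = 110) {
  cohorts <- as.data.frame(cohorts)
  if (!all(c("age", "sex", "count") %in% names(cohorts)))
    stop("cohorts needs columns age, sex, count")
  if (any(cohorts$count < 0)) stop("cohort counts must be >= 0")
  if (discount_rate < 0) stop("discount_rate must be >= 0")
  structure(list(cohorts = cohorts,
                 mortality = rate_fun(mortality, "mortality"),
                 pyld = rate_fun(pyld, "pyld"),
                 discount_rate = discount_rate,
                 max_age = max_age),
            class = "population_lifetable")
}

#' Change in BMI implied by a sustained change in energy intake
#'
#' Steady-state rule of thumb: a sustained change of `kj_per_kg` kJ/day
#' (default 94) moves equilibrium body weight by 1 kg, so
#' `dBMI = (delta_kj / kj_per_kg) / height^2`.
#'
#' @param delta_kj change in energy intake, kJ/day.
#' @param height_m height in metres (> 0).
#' @param baseline_weight_kg unused by the steady-state rule; accepted for
#'   interface compatibility with dynamic weight models.
#' @param kj_per_kg kJ/day per kg of equilibrium weight change.
#' @return change in BMI, kg/m^2.
#' @examples
#' energy_to_bmi(-348, 1.7) # about -1.28
#' @export
energy_to_bmi <- function(delta_kj, height_m, baseline_weight_kg = NULL,
                          kj_per_kg = 94) {
  if (any(height_m <= 0)) stop("height must be > 0")
  if (kj_per_kg <= 0) stop("kj_per_kg must be > 0")
  (delta_kj / kj_per_kg) / height_m^2
}

#' Potential impact fraction from an exposure-distribution shift
#'
#' `PIF = (sum(p_pre * rr) - sum(p_post * rr)) / sum(p_pre * rr)` over
#' identical exposure categories. Positive when exposure (and hence average
#' relative risk) falls.
#'
#' @param p_pre,p_post exposure distributions (same categories; each sums
#'   to 1 for a proper distribution, though only relative weights matter
#'   for `p_pre`).
#' @param rr relative risk of each category (> 0).
#' @return PIF in (-Inf, 1].
#' @examples
#' potential_impact_fraction(1, 1, rr = 2)            # 0: no shift
#' # continuous exposure via rr per unit: PIF = 1 - rr^(post - pre)
#' pif_exposure_shift(rr_per_unit = 1.1, pre = 27.5, post = 26.9)
#' @export
potential_impact_fraction <- function(p_pre, p_post, rr) {
  if (length(p_pre) != length(p_post) || length(p_pre) != length(rr))
    stop("p_pre, p_post and rr must share categories")
  if (any(rr <= 0)) stop("relative risks must be > 0")
  denom <- sum(p_pre * rr)
  if (denom <= 0) stop("non-positive baseline risk")
  (denom - sum(p_post * rr)) / denom
}

#' @rdname potential_impact_fraction
#' @param rr_per_unit relative risk per unit of a continuous exposure.
#' @param pre,post exposure levels in native units.
#' @export
pif_exposure_shift <- function(rr_per_unit, pre, post) {
  if (rr_per_unit <= 0) stop("relative risk must be > 0")
  1 - rr_per_unit^(post - pre)
}

# one cohort, both arms; returns c(bau = , int = ) discounted HALYs
run_cohort <- function(age0, sex, count, pop, diseases, pifs, horizon) {
  nd <- length(diseases)
  prev_bau <- vapply(diseases, function(d) d$initial_prevalence, numeric(1))
  prev_int <- prev_bau
  l_bau <- l_int <- count
  haly_bau <- haly_int <- 0
  disc <- 1 / (1 + pop$discount_rate)
  for (t in seq_len(horizon) - 1L) {
    age <- min(age0 + t, pop$max_age)
    m <- pop$mortality(age, sex)
    morb <- pop$pyld(age, sex)
    d_prev <- prev_int - prev_bau
    dm <- dmorb <- 0
    inc_bau <- inc_int <- cfr <- rem <- numeric(nd)
    for (k in seq_len(nd)) {
      d <- diseases[[k]]
      cfr[k] <- d$case_fatality(age, sex)
      rem[k] <- d$remission(age, sex)
      inc_bau[k] <- d$incidence(age, sex)
      eff <- if (t >= d$lag_years) pifs[k]
             else if (d$phase_in && d$lag_years > 0) pifs[k] * t / d$lag_years
             else 0
      inc_int[k] <- inc_bau[k] * (1 - eff)
      dm <- dm + cfr[k] * d_prev[k]
      dmorb <- dmorb + d$disability_weight * d_prev[k]
    }
    m_bau <- min(max(m, 0), 1)
    m_int <- min(max(m + dm, 0), 1)
    morb_bau <- min(max(morb, 0), 1)
    morb_int <- min(max(morb + dmorb, 0), 1)
    w <- disc^t
    haly_bau <- haly_bau + w * l_bau * (1 - m_bau / 2) * (1 - morb_bau)
    haly_int <- haly_int + w * l_int * (1 - m_int / 2) * (1 - morb_int)
    l_bau <- l_bau * (1 - m_bau)
    l_int <- l_int * (1 - m_int)
    for (k in seq_len(nd)) {
      prev_bau[k] <- prev_bau[k] + inc_bau[k] * (1 - prev_bau[k]) -
        (cfr[k] + rem[k]) * prev_bau[k]
      prev_int[k] <- prev_int[k] + inc_int[k] * (1 - prev_int[k]) -
        (cfr[k] + rem[k]) * prev_int[k]
    }
    if (any(prev_bau < 0 | prev_bau > 1 | prev_int < 0 | prev_int > 1)) {
      warning("prevalence left [0, 1]; clamped")
      prev_bau <- pmin(pmax(prev_bau, 0), 1)
      prev_int <- pmin(pmax(prev_int, 0), 1)
    }
  }
  c(bau = haly_bau, int = haly_int)
}

#' Run the proportional multistate lifetable
#'
#' Two parallel runs, business-as-usual and intervention (per-disease
#' incidence scaled by `1 - PIF` after each disease's lag). Per annual
#' cycle, disease prevalence evolves from incidence, case fatality and
#' remission; the prevalence difference between arms perturbs all-cause
#' mortality and morbidity; HALYs accrue as discounted, morbidity-weighted
#' life years (half-cycle corrected for deaths).
#'
#' @param pop a [population_lifetable()].
#' @param diseases list of [disease_spec()].
#' @param pifs numeric vector of PIFs, one per disease (each <= 1).
#' @param horizon number of annual cycles.
#' @return list: `haly_gain` (intervention minus BAU, discounted), totals
#'   `haly_bau`, `haly_int`, and `by_cohort` data.frame.
#' @export
run_lifetable <- function(pop, diseases, pifs, horizon) {
  stopifnot(inherits(pop, "population_lifetable"))
  if (inherits(diseases, "disease_spec")) diseases <- list(diseases)
  if (length(pifs) != length(diseases))
    stop("need one PIF per disease")
  if (any(pifs > 1)) stop("PIFs cannot exceed 1")
  if (horizon < 1) stop("horizon must be >= 1")
  co <- pop$cohorts
  res <- t(mapply(run_cohort, co$age, co$sex, co$count,
                  MoreArgs = list(pop = pop, diseases = diseases,
                                  pifs = pifs, horizon = horizon)))
  by_cohort <- data.frame(age = co$age, sex = co$sex, count = co$count,
                          haly_bau = res[, "bau"], haly_int = res[, "int"],
                          haly_gain = res[, "int"] - res[, "bau"])
  list(haly_gain = sum(by_cohort$haly_gain),
       haly_bau = sum(by_cohort$haly_bau),
       haly_int = sum(by_cohort$haly_int),
       by_cohort = by_cohort)
}

#' Percent reduction in HALY gain due to TFEe adjustment
#'
#' Compares the conventional (unadjusted) HALY gain with the TFEe-adjusted
#' one: `100 * (conventional - adjusted) / conventional`.
#'
#' @param conventional,adjusted HALY gains from the two analyses.
#' @return percent reduction.
#' @export
haly_reduction_pct <- function(conventional, adjusted) {
  if (conventional == 0) stop("conventional HALY gain is zero")
  100 * (conventional - adjusted) / conventional
}
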