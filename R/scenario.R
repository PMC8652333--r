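# Scenario configuration: the stated world every simulation draws from.
#
# The calendar is integer days with day 0 = start of the vaccination campaign
# (the study origin). The surveillance window is [0, n_months * 30); the
# historical window is its mirror one year earlier, [start - 365, end - 365),
# matching the convention of obtaining background rates for the same range of
# months one year before the campaign. All intervals are half-open [start, end).

#' Define an outcome's event process
#'
#' Each outcome is a (possibly recurrent) inhomogeneous Poisson process per
#' person with per-day hazard
#' `base_rate / 365.25 * age_mult * sex_mult * seasonal * secular`,
#' optionally modified by the scenario's bias knobs.
#'
#' @param outcome_id integer or character id, unique within a scenario.
#' @param base_rate events per person-year for the reference stratum
#'   (male, age band 0, no seasonal/secular modulation).
#' @param age_multipliers positive numeric of length 10, rate multipliers per
#'   ten-year age band `[0,10), ..., [90,Inf)`. Default all 1.
#' @param sex_multiplier positive rate multiplier for females relative to
#'   males. Default 1.
#' @param seasonal_amplitude relative amplitude (in `[0,1)`) of a 12-month
#'   sinusoid `1 + A * sin(2*pi*month/12)` where `month = day/30`. Default 0.
#' @param secular_slope relative rate change per year; the secular term is
#'   `(1 + slope)^(day/365.25)`. Default 0.
#' @return an object of class `outcome_def`.
#' @export
outcome_def <- function(outcome_id, base_rate,
                        age_multipliers = rep(1, 10),
                        sex_multiplier = 1,
                        seasonal_amplitude = 0,
                        secular_slope = 0) {
  if (length(base_rate) != 1L || is.na(base_rate) || base_rate < 0)
    stop_config("base_rate must be a single non-negative number")
  if (length(age_multipliers) != 10L || any(age_multipliers <= 0))
    stop_config("age_multipliers must be 10 positive numbers")
  if (sex_multiplier <= 0) stop_config("sex_multiplier must be > 0")
  if (seasonal_amplitude < 0 || seasonal_amplitude >= 1)
    stop_config("seasonal_amplitude must be in [0, 1)")
  if (secular_slope <= -1) stop_config("secular_slope must be > -1")
  structure(list(
    outcome_id = outcome_id,
    base_rate = base_rate,
    age_multipliers = as.numeric(age_multipliers),
    sex_multiplier = sex_multiplier,
    seasonal_amplitude = seasonal_amplitude,
    secular_slope = secular_slope
  ), class = "outcome_def")
}

#' Bias mechanisms switchable in the generator
#'
#' At the neutral values (0 shift, factors 1) the scenario is unbiased: the
#' post-vaccination rate of every outcome equals its background rate up to
#' the configured seasonal/secular terms.
#'
#' @param age_confounding_strength log-scale shift of vaccination propensity
#'   per ten-year age band index (confounding by indication when outcomes
#'   also vary with age). 0 = off.
#' @param healthy_vaccinee_shift multiplicative outcome-rate factor applied to
#'   all person-time of (eventually) vaccinated persons. Values < 1 emulate
#'   the healthy vaccinee effect; 1 = off.
#' @param visit_capture_boost multiplicative outcome-recording factor applied
#'   within `visit_capture_days` days after any outpatient visit (vaccination
#'   visits included). 1 = off.
#' @param visit_capture_days window length in days for the capture boost.
#' @return an object of class `bias_knobs`.
#' @export
bias_knobs <- function(age_confounding_strength = 0,
                       healthy_vaccinee_shift = 1,
                       visit_capture_boost = 1,
                       visit_capture_days = 30L) {
  if (healthy_vaccinee_shift <= 0 || visit_capture_boost <= 0)
    stop_config("multiplicative bias factors must be > 0")
  if (visit_capture_days < 0) stop_config("visit_capture_days must be >= 0")
  structure(list(
    age_confounding_strength = age_confounding_strength,
    healthy_vaccinee_shift = healthy_vaccinee_shift,
    visit_capture_boost = visit_capture_boost,
    visit_capture_days = as.integer(visit_capture_days)
  ), class = "bias_knobs")
}

#' Vaccine uptake curve
#'
#' `"rapid"` emulates campaigns such as pandemic H1N1 or seasonal influenza:
#' at least 80% of all doses fall in surveillance months 1-2. `"slow"`
#' emulates HPV- or varicella-zoster-like uptake: doses spread approximately
#' uniformly over months 1-12 (or 1-`n_months`).
#'
#' @param type `"rapid"` or `"slow"`.
#' @param coverage total fraction of the population vaccinated by the end of
#'   the surveillance window, in `[0,1]`.
#' @param peak_month month (1-based) of peak dose density for the rapid
#'   curve; doses concentrate in `peak_month` and `peak_month + 1`.
#' @return an object of class `uptake_curve`.
#' @export
uptake_curve <- function(type = c("rapid", "slow"), coverage = 0.5,
                         peak_month = 1L) {
  type <- match.arg(type)
  if (coverage < 0 || coverage > 1) stop_config("coverage must be in [0, 1]")
  if (peak_month < 1) stop_config("peak_month must be >= 1")
  structure(list(type = type, coverage = coverage,
                 peak_month = as.integer(peak_month)),
            class = "uptake_curve")
}

# Default age weights loosely shaped like a commercial-claims population
# (working-age heavy, thin tails above 65).
.default_age_weights <- c(0.12, 0.13, 0.14, 0.15, 0.15, 0.14, 0.09, 0.05, 0.02, 0.01)

#' Assemble and validate a scenario configuration
#'
#' @param n_persons population size.
#' @param n_months number of surveillance accrual months (9 for
#'   influenza-like campaigns, 12 for HPV/varicella-zoster-like ones).
#' @param uptake an [uptake_curve()].
#' @param female_fraction expected share of females, in `[0,1]`.
#' @param age_weights probability weights over the 10 ten-year age bands.
#' @param visit_rate outpatient visits per person-year (homogeneous process).
#' @param outcome_defs list of [outcome_def()] objects with unique ids.
#' @param bias a [bias_knobs()] object.
#' @param vaccine_id id assigned to the simulated vaccine exposure.
#' @param seed master integer seed; per-table generator seeds are derived
#'   from it by fixed offsets.
#' @return an object of class `scenario_config` carrying, in addition to the
#'   arguments, the derived `surveillance_window` and `historical_window`
#'   (half-open day intervals) and `study_origin = 0`.
#' @examples
#' cfg <- scenario_config(n_persons = 1000,
#'                        outcome_defs = list(outcome_def("oc1", 0.05)))
#' cfg$historical_window  # one year before the surveillance window
#' @export
scenario_config <- function(n_persons,
                            n_months = 9L,
                            uptake = uptake_curve("rapid", 0.5),
                            female_fraction = 0.511,
                            age_weights = .default_age_weights,
                            visit_rate = 3,
                            outcome_defs = list(),
                            bias = bias_knobs(),
                            vaccine_id = "vax",
                            seed = 1L) {
  if (length(n_persons) != 1L || is.na(n_persons) || n_persons < 0)
    stop_config("n_persons must be a single non-negative count")
  if (n_months < 1 || n_months > 12) stop_config("n_months must be in 1..12")
  if (female_fraction < 0 || female_fraction > 1)
    stop_config("female_fraction must be in [0, 1]")
  if (length(age_weights) != 10L || any(age_weights < 0) || sum(age_weights) <= 0)
    stop_config("age_weights must be 10 non-negative weights with positive sum")
  if (visit_rate < 0) stop_config("visit_rate must be >= 0")
  if (!inherits(uptake, "uptake_curve")) stop_config("uptake must be an uptake_curve()")
  if (!inherits(bias, "bias_knobs")) stop_config("bias must be a bias_knobs()")
  ids <- vapply(outcome_defs, function(d) as.character(d$outcome_id), "")
  if (anyDuplicated(ids)) stop_config("outcome ids must be unique")
  for (d in outcome_defs)
    if (!inherits(d, "outcome_def")) stop_config("outcome_defs must be outcome_def() objects")

  surveillance <- c(0L, as.integer(n_months) * DAYS_PER_MONTH)
  historical <- surveillance - 365L
  stopifnot(historical[2] <= surveillance[1])  # windows must not overlap

  structure(list(
    n_persons = as.integer(n_persons),
    n_months = as.integer(n_months),
    study_origin = 0L,
    surveillance_window = surveillance,
    historical_window = historical,
    uptake = uptake,
    female_fraction = female_fraction,
    age_weights = as.numeric(age_weights) / sum(age_weights),
    visit_rate = visit_rate,
    outcome_defs = outcome_defs,
    bias = bias,
    vaccine_id = vaccine_id,
    seed = as.integer(seed)
  ), class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("<scenario_config>\n")
  cat(sprintf("  persons: %d, months: %d, uptake: %s (coverage %.2f)\n",
              x$n_persons, x$n_months, x$uptake$type, x$uptake$coverage))
  cat(sprintf("  surveillance days [%d, %d), historical days [%d, %d)\n",
              x$surveillance_window[1], x$surveillance_window[2],
              x$historical_window[1], x$historical_window[2]))
  cat(sprintf("  outcomes: %d, visit rate: %.1f/yr, seed: %d\n",
              length(x$outcome_defs), x$visit_rate, x$seed))
  k <- x$bias
  cat(sprintf("  bias: age_conf=%.2f hv_shift=%.2f visit_boost=%.2f (d=%d)\n",
              k$age_confounding_strength, k$healthy_vaccinee_shift,
              k$visit_capture_boost, k$visit_capture_days))
  invisible(x)
}
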