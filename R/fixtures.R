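# Tiny hand-computable fixtures and canned scenario profiles. Fixture tables
# are literal (built in code, each expected value annotated with its hand
# tally) so the test suite and documentation never depend on generated data
# for the arithmetic checks.

make_event_tables <- function(persons, observation_periods,
                              visits = NULL, exposures = NULL,
                              outcomes = NULL, config = NULL) {
  tabs <- empty_event_tables(config)
  tabs$persons <- data.table::as.data.table(persons)
  tabs$observation_periods <- data.table::as.data.table(observation_periods)
  if (!is.null(visits)) tabs$visits <- data.table::as.data.table(visits)
  if (!is.null(exposures)) tabs$exposures <- data.table::as.data.table(exposures)
  if (!is.null(outcomes)) tabs$outcomes <- data.table::as.data.table(outcomes)
  tabs
}

fixture_registry <- local({
  reg <- list()

  # -- five_person_rates ------------------------------------------------------
  # 5 persons, observation [-365, 270), historical interval [-365, -95)
  # (i.e. 270 days). Outcome "oc": person 1 one event in the interval,
  # person 2 two events in the interval (one first event), person 3 one
  # event outside it. Unanchored unadjusted:
  #   person-time = 5 * 270 / 365.25 = 3.69610 py
  #   first events = 2            rate = 2 / 3.69610 = 0.541110 / py
  reg$five_person_rates <- function() {
    tabs <- make_event_tables(
      persons = data.frame(person_id = 1:5,
                           sex = c("M", "F", "M", "F", "F"),
                           birth_day = c(-15000L, -9000L, -20000L, -11000L, -7000L)),
      observation_periods = data.frame(person_id = 1:5, start_day = -365L,
                                       end_day = 270L),
      outcomes = data.frame(person_id = c(1L, 2L, 2L, 3L),
                            outcome_id = "oc",
                            outcome_day = c(-200L, -300L, -150L, 100L))
    )
    list(tables = tabs,
         historical_interval = c(-365L, -95L),
         expected = list(events = 2L,
                         person_time = 5 * 270 / 365.25,
                         rate = 2 / (5 * 270 / 365.25)))
  }

  # -- threshold_24_events ----------------------------------------------------
  # 30 persons vaccinated on day 0; persons 1..24 each have one outcome on
  # day 10 (inside the 1-28 day time-at-risk) -> 24 exposed first events,
  # below the 25-event synthesis threshold, so zero positives are created.
  reg$threshold_24_events <- function() {
    n <- 30L
    tabs <- make_event_tables(
      persons = data.frame(person_id = 1:n, sex = rep(c("F", "M"), 15),
                           birth_day = -12000L),
      observation_periods = data.frame(person_id = 1:n, start_day = -365L,
                                       end_day = 270L),
      exposures = data.frame(person_id = 1:n, vaccine_id = "vax",
                             exposure_day = 0L),
      outcomes = data.frame(person_id = 1:24, outcome_id = "nc",
                            outcome_day = 10L)
    )
    list(tables = tabs, expected = list(parent_tar_events = 24L, n_positives = 0L))
  }

  # -- six_stratum_expected ---------------------------------------------------
  # Background rates and observed person-time over 6 age-sex strata; the
  # expected count is the hand sum:
  #   E = 0.1*2 + 0.2*1 + 0.3*4 + 0.05*10 + 0.15*2 + 0.25*2 = 2.9
  reg$six_stratum_expected <- function() {
    background <- data.table::data.table(
      outcome_id = "oc",
      age_band = rep(c("20-29", "30-39", "40-49"), each = 2),
      sex = rep(c("F", "M"), 3),
      events = c(10L, 20L, 30L, 5L, 15L, 25L),
      person_time = c(100, 100, 100, 100, 100, 100),
      rate = c(0.1, 0.2, 0.3, 0.05, 0.15, 0.25),
      estimable = TRUE)
    observed <- data.table::data.table(
      outcome_id = "oc",
      age_band = rep(c("20-29", "30-39", "40-49"), each = 2),
      sex = rep(c("F", "M"), 3),
      events = 0L,
      person_time = c(2, 1, 4, 10, 2, 2),
      rate = 0, estimable = TRUE)
    list(background = background, observed = observed,
         expected = list(expected_count = 2.9, n_hist = 105L))
  }

  reg
})

#' Load a named fixture
#'
#' Fixtures are literal miniature datasets with hand-computed expectations
#' documented beside their construction; see the package sources for the
#' tallies.
#'
#' @param name one of `"five_person_rates"`, `"threshold_24_events"`,
#'   `"six_stratum_expected"`.
#' @return a list with the fixture's tables/inputs and an `expected` list.
#' @export
load_fixture <- function(name) {
  if (!name %in% names(fixture_registry))
    stop_config("unknown fixture '%s'; available: %s", name,
                paste(names(fixture_registry), collapse = ", "))
  fixture_registry[[name]]()
}

#' Canned scenario profiles
#'
#' Ready-made [scenario_config()]s emulating the study settings: a
#' commercial-claims-like population with rapid (influenza-like, 9 months)
#' or slow (HPV-like, 12 months) uptake, an older Medicaid-like population,
#' and variants with a single bias knob switched on.
#'
#' @param name profile name: `"ccae_rapid"`, `"ccae_slow"`, `"mdcd_rapid"`,
#'   `"age_confounded"`, `"healthy_vaccinee"`, `"visit_capture"`.
#' @param n_persons population size override.
#' @param outcome_defs outcome definitions override (default: 20 negative
#'   controls at rates 0.02-0.1 per person-year).
#' @param seed master seed.
#' @return a [scenario_config()].
#' @export
scenario_profile <- function(name, n_persons = 20000L, outcome_defs = NULL,
                             seed = 1L) {
  if (is.null(outcome_defs)) {
    rates <- seq(0.02, 0.1, length.out = 20)
    outcome_defs <- lapply(seq_along(rates), function(i)
      outcome_def(sprintf("nc%02d", i), rates[i]))
  }
  base <- function(...) scenario_config(n_persons = n_persons,
                                        outcome_defs = outcome_defs,
                                        seed = seed, ...)
  switch(name,
    ccae_rapid = base(n_months = 9L, uptake = uptake_curve("rapid", 0.5),
                      female_fraction = 0.511),
    ccae_slow = base(n_months = 12L, uptake = uptake_curve("slow", 0.5),
                     female_fraction = 0.511),
    mdcd_rapid = base(n_months = 9L, uptake = uptake_curve("rapid", 0.5),
                      female_fraction = 0.5623,
                      age_weights = c(0.06, 0.07, 0.08, 0.09, 0.10,
                                      0.12, 0.15, 0.15, 0.12, 0.06)),
    age_confounded = base(n_months = 9L, uptake = uptake_curve("rapid", 0.4),
                          bias = bias_knobs(age_confounding_strength = 0.5)),
    healthy_vaccinee = base(n_months = 9L, uptake = uptake_curve("rapid", 0.4),
                            bias = bias_knobs(healthy_vaccinee_shift = 1.6)),
    visit_capture = base(n_months = 9L, uptake = uptake_curve("rapid", 0.4),
                         bias = bias_knobs(visit_capture_boost = 3,
                                           visit_capture_days = 30L)),
    stop_config("unknown scenario profile '%s'", name))
}
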