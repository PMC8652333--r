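# OMOP-lite event table generators.
#
# Five tables mirror the minimal structure the observed-vs-expected analysis
# needs from a claims/EHR source mapped to a common data model: persons,
# observation periods, outpatient visits, vaccine exposures (first dose
# only), and outcome occurrences. Every generator draws from its own seeded
# stream derived from the master scenario seed, so regenerating one table
# never perturbs another.

.SEED_POPULATION <- 11L
.SEED_VISITS <- 23L
.SEED_UPTAKE <- 37L
.SEED_OUTCOMES <- 53L

empty_event_tables <- function(config) {
  tabs <- list(
    persons = data.table::data.table(person_id = integer(), sex = character(),
                                     birth_day = integer()),
    observation_periods = data.table::data.table(person_id = integer(),
                                                 start_day = integer(),
                                                 end_day = integer()),
    visits = data.table::data.table(person_id = integer(), visit_day = integer()),
    exposures = data.table::data.table(person_id = integer(),
                                       vaccine_id = character(),
                                       exposure_day = integer()),
    outcomes = data.table::data.table(person_id = integer(),
                                      outcome_id = character(),
                                      outcome_day = integer())
  )
  structure(tabs, class = "event_tables", config = config)
}

#' Generate the simulated population
#'
#' Draws `n_persons` with sex from `female_fraction` and age at the study
#' origin from the configured ten-year band weights (uniform within band).
#' Every person gets a single observation period covering the historical and
#' surveillance windows; enrollment churn is deliberately not modelled.
#'
#' @param config a [scenario_config()].
#' @return an `event_tables` object with `persons` and `observation_periods`
#'   filled and the remaining tables empty.
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  tabs <- empty_event_tables(config)
  n <- config$n_persons
  if (n == 0L) return(tabs)
  with_seed(derive_seed(config$seed, .SEED_POPULATION), {
    sex <- ifelse(stats::runif(n) < config$female_fraction, "F", "M")
    band <- sample.int(10L, n, replace = TRUE, prob = config$age_weights) - 1L
    age_at_origin <- (band + stats::runif(n)) * 10
    birth_day <- config$study_origin - as.integer(round(age_at_origin * DAYS_PER_YEAR))
    tabs$persons <- data.table::data.table(person_id = seq_len(n), sex = sex,
                                           birth_day = birth_day)
  })
  tabs$observation_periods <- data.table::data.table(
    person_id = seq_len(n),
    start_day = config$historical_window[1],
    end_day = config$surveillance_window[2]
  )
  tabs
}

#' Generate outpatient visits
#'
#' A homogeneous per-person process at `visit_rate` visits per person-year,
#' restricted to each person's observation period.
#'
#' @param tables an `event_tables` with persons generated.
#' @param config the matching [scenario_config()].
#' @return `tables` with the `visits` table filled.
#' @export
generate_visits <- function(tables, config) {
  stopifnot(inherits(tables, "event_tables"))
  op <- tables$observation_periods
  if (nrow(op) == 0L || config$visit_rate == 0) return(tables)
  with_seed(derive_seed(config$seed, .SEED_VISITS), {
    years <- (op$end_day - op$start_day) / DAYS_PER_YEAR
    n_visits <- stats::rpois(nrow(op), config$visit_rate * years)
    idx <- rep.int(seq_len(nrow(op)), n_visits)
    day <- op$start_day[idx] +
      as.integer(floor(stats::runif(length(idx)) * (op$end_day[idx] - op$start_day[idx])))
    visits <- data.table::data.table(person_id = op$person_id[idx], visit_day = day)
    data.table::setorder(visits, person_id, visit_day)
    tables$visits <- visits
  })
  tables
}

# Month (1-based, 30-day blocks from surveillance start) -> probability of a
# dose falling in that month, for each uptake curve shape.
uptake_month_probs <- function(uptake, n_months) {
  p <- numeric(n_months)
  if (uptake$type == "slow") {
    p[] <- 1 / n_months
  } else {
    peak <- min(uptake$peak_month, n_months)
    nxt <- min(peak + 1L, n_months)
    p[peak] <- p[peak] + 0.60
    p[nxt] <- p[nxt] + 0.25
    rest <- setdiff(seq_len(n_months), c(peak, nxt))
    if (length(rest)) p[rest] <- 0.15 / length(rest) else p[peak] <- p[peak] + 0.15
  }
  p / sum(p)
}

#' Generate vaccine uptake (first-dose exposures)
#'
#' Selects `coverage * n_persons` persons to vaccinate. When
#' `age_confounding_strength` is non-zero, selection probability is
#' proportional to `exp(strength * age_band_index)` (age at study origin),
#' emulating confounding by indication; selection is then renormalised so the
#' total coverage is still hit. Dose days follow the uptake curve: rapid
#' concentrates >= 80% of doses in the peak month and the next, slow spreads
#' them uniformly over the surveillance months. Each vaccination also records
#' an outpatient visit on the dose day, since vaccines are administered at a
#' healthcare contact; this is what couples vaccination to the
#' visit-proximity recording bias when that knob is on.
#'
#' @inheritParams generate_visits
#' @return `tables` with `exposures` filled (at most one row per person).
#' @export
generate_uptake <- function(tables, config) {
  stopifnot(inherits(tables, "event_tables"))
  pers <- tables$persons
  n <- nrow(pers)
  n_exposed <- round(config$uptake$coverage * n)
  if (n == 0L || n_exposed == 0L) return(tables)
  with_seed(derive_seed(config$seed, .SEED_UPTAKE), {
    age0 <- (config$study_origin - pers$birth_day) / DAYS_PER_YEAR
    w <- exp(config$bias$age_confounding_strength * age_band(age0))
    who <- sample.int(n, n_exposed, replace = FALSE, prob = w)
    probs <- uptake_month_probs(config$uptake, config$n_months)
    month <- sample.int(config$n_months, n_exposed, replace = TRUE, prob = probs)
    day <- config$surveillance_window[1] + (month - 1L) * DAYS_PER_MONTH +
      as.integer(floor(stats::runif(n_exposed) * DAYS_PER_MONTH))
    expo <- data.table::data.table(person_id = pers$person_id[who],
                                   vaccine_id = config$vaccine_id,
                                   exposure_day = day)
    data.table::setorder(expo, person_id)
    tables$exposures <- expo
    vax_visits <- data.table::data.table(person_id = expo$person_id,
                                         visit_day = expo$exposure_day)
    visits <- rbind(tables$visits, vax_visits)
    data.table::setorder(visits, person_id, visit_day)
    tables$visits <- visits
  })
  tables
}

#' Generate outcome occurrences
#'
#' Each outcome is drawn per person by thinning a dominating homogeneous
#' process. The per-day hazard is
#' `base_rate/365.25 * age_mult(age at day) * sex_mult *
#'  (1 + A sin(2 pi day/360)) * (1 + slope)^(day/365.25)`,
#' multiplied by `healthy_vaccinee_shift` over all person-time of vaccinated
#' persons and by `visit_capture_boost` on days within `visit_capture_days`
#' days after any visit. Events are recurrent (downstream incidence logic
#' applies first-event-per-window filtering).
#'
#' @inheritParams generate_visits
#' @return `tables` with the `outcomes` table filled.
#' @export
generate_outcomes <- function(tables, config) {
  stopifnot(inherits(tables, "event_tables"))
  pers <- tables$persons
  op <- tables$observation_periods
  if (nrow(pers) == 0L || length(config$outcome_defs) == 0L) return(tables)
  knobs <- config$bias

  # person-level invariants of the hazard bound
  exposed <- pers$person_id %in% tables$exposures$person_id
  band_lo <- age_band((op$start_day - pers$birth_day) / DAYS_PER_YEAR)
  band_hi <- age_band((op$end_day - 1L - pers$birth_day) / DAYS_PER_YEAR)
  t_days <- op$end_day - op$start_day
  hv_factor <- ifelse(exposed, knobs$healthy_vaccinee_shift, 1)
  boost_bound <- max(knobs$visit_capture_boost, 1)

  visits <- data.table::copy(tables$visits)
  has_visits <- nrow(visits) > 0L && (knobs$visit_capture_boost != 1)
  if (has_visits) data.table::setkey(visits, person_id, visit_day)

  out_list <- vector("list", length(config$outcome_defs))
  with_seed(derive_seed(config$seed, .SEED_OUTCOMES), {
    for (j in seq_along(config$outcome_defs)) {
      d <- config$outcome_defs[[j]]
      if (d$base_rate == 0) {
        out_list[[j]] <- NULL
        next
      }
      sex_mult <- ifelse(pers$sex == "F", d$sex_multiplier, 1)
      age_bound <- pmax(d$age_multipliers[band_lo + 1L], d$age_multipliers[band_hi + 1L])
      seas_bound <- 1 + d$seasonal_amplitude
      sec_bound <- max((1 + d$secular_slope)^(op$start_day / DAYS_PER_YEAR),
                       (1 + d$secular_slope)^(op$end_day / DAYS_PER_YEAR))
      # hv_factor multiplies the true hazard at every day for that person, so
      # it enters the dominating bound exactly (tight when < 1)
      bound <- d$base_rate / DAYS_PER_YEAR * age_bound * sex_mult * seas_bound *
        sec_bound * hv_factor * boost_bound
      n_cand <- stats::rpois(nrow(pers), bound * t_days)
      if (sum(n_cand) == 0L) next
      idx <- rep.int(seq_len(nrow(pers)), n_cand)
      day <- op$start_day[idx] +
        as.integer(floor(stats::runif(length(idx)) * t_days[idx]))
      age_mult <- d$age_multipliers[age_band((day - pers$birth_day[idx]) / DAYS_PER_YEAR) + 1L]
      seas <- 1 + d$seasonal_amplitude * sin(2 * pi * day / 360)
      sec <- (1 + d$secular_slope)^(day / DAYS_PER_YEAR)
      boost <- rep(1, length(idx))
      if (has_visits) {
        cand <- data.table::data.table(person_id = pers$person_id[idx], visit_day = day)
        prev <- visits[cand, x.visit_day, roll = TRUE, mult = "last",
                       on = c("person_id", "visit_day")]
        in_window <- !is.na(prev) & (day - prev) <= knobs$visit_capture_days
        boost[in_window] <- knobs$visit_capture_boost
      }
      hazard <- d$base_rate / DAYS_PER_YEAR * age_mult * sex_mult[idx] * seas * sec *
        hv_factor[idx] * boost
      keep <- stats::runif(length(idx)) < hazard / bound[idx]
      if (!any(keep)) next
      out_list[[j]] <- data.table::data.table(
        person_id = pers$person_id[idx][keep],
        outcome_id = as.character(d$outcome_id),
        outcome_day = day[keep]
      )
    }
  })
  out <- data.table::rbindlist(out_list[!vapply(out_list, is.null, TRUE)])
  if (nrow(out) == 0L) return(tables)
  data.table::setorder(out, outcome_id, person_id, outcome_day)
  tables$outcomes <- out
  tables
}

#' Run all four generators for a scenario
#'
#' @param config a [scenario_config()].
#' @return a complete `event_tables` object.
#' @export
simulate_scenario <- function(config) {
  tabs <- generate_population(config)
  tabs <- generate_visits(tabs, config)
  tabs <- generate_uptake(tabs, config)
  generate_outcomes(tabs, config)
}

#' Check the structural invariants of an event-table set
#'
#' Verifies observation-period containment of every visit, exposure and
#' outcome, and the one-exposure-per-person-per-vaccine rule.
#'
#' @param tables an `event_tables`.
#' @return invisibly `TRUE`; stops with a message on violation.
#' @export
validate_event_tables <- function(tables) {
  stopifnot(inherits(tables, "event_tables"))
  op <- tables$observation_periods
  check_contained <- function(dt, col, what) {
    if (nrow(dt) == 0L) return(invisible())
    m <- merge(dt, op, by = "person_id")
    bad <- m[[col]] < m$start_day | m[[col]] >= m$end_day
    if (any(bad)) stop(sprintf("%d %s outside observation periods", sum(bad), what))
  }
  check_contained(tables$visits, "visit_day", "visits")
  check_contained(tables$exposures, "exposure_day", "exposures")
  check_contained(tables$outcomes, "outcome_day", "outcomes")
  dup <- tables$exposures[, .N, by = c("person_id", "vaccine_id")][N > 1L]
  if (nrow(dup) > 0L) stop("multiple exposures per person per vaccine")
  invisible(TRUE)
}
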