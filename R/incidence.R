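# Background (historical) and observed (post-vaccination) incidence rates.
#
# Four designs are evaluated, crossing two flags:
#   adjusted  - stratify rates by ten-year age band and sex
#   anchored  - estimate the background rate in a time-at-risk window starting
#               at a random outpatient visit, mimicking the healthcare-contact
#               context of vaccination
# The observed side is identical across designs: index = vaccination day,
# first outcome event in the time-at-risk window, under monthly data accrual.
#
# Person-time windows depend only on (tables, design, month), never on the
# outcome, so the batch estimator computes them once and tallies each
# control's events against them.

#' Time-at-risk window
#'
#' Day offsets after the index day, both inclusive; the default 1-28 is the
#' post-vaccination risk window used throughout. Internally the window is the
#' half-open interval `[index + start, index + end + 1)`.
#'
#' @param start_offset first day at risk after index (>= 1).
#' @param end_offset last day at risk after index.
#' @return a `tar_window` object.
#' @export
tar_window <- function(start_offset = 1L, end_offset = 28L) {
  if (start_offset < 1 || end_offset < start_offset)
    stop_config("need 1 <= start_offset <= end_offset")
  structure(list(start_offset = as.integer(start_offset),
                 end_offset = as.integer(end_offset)),
            class = "tar_window")
}

#' Background-rate design variant
#'
#' @param adjusted stratify by age band and sex?
#' @param anchored anchor the background time-at-risk at a random outpatient
#'   visit?
#' @return a `design_variant` with a `label` field
#'   (`"unadjusted"`, `"age_sex"`, `"anchored"`, `"anchored_age_sex"`).
#' @export
design_variant <- function(adjusted = FALSE, anchored = FALSE) {
  label <- if (anchored && adjusted) "anchored_age_sex"
  else if (anchored) "anchored"
  else if (adjusted) "age_sex"
  else "unadjusted"
  structure(list(adjusted = isTRUE(adjusted), anchored = isTRUE(anchored),
                 label = label), class = "design_variant")
}

#' All four design variants
#' @return a named list of [design_variant()]s.
#' @export
design_grid <- function() {
  v <- list(design_variant(FALSE, FALSE), design_variant(TRUE, FALSE),
            design_variant(FALSE, TRUE), design_variant(TRUE, TRUE))
  names(v) <- vapply(v, `[[`, "", "label")
  v
}

# Attach stratum labels (NA/NA when marginal) to a windows table, using age
# at the index day.
label_strata <- function(windows, persons, adjusted) {
  if (nrow(windows) == 0L) {
    windows[, `:=`(age_band = character(), sex = character())]
    return(windows)
  }
  if (adjusted) {
    pm <- persons[windows, on = "person_id"]
    windows[, `:=`(
      age_band = age_band_label(age_band((index_day - pm$birth_day) / DAYS_PER_YEAR)),
      sex = pm$sex)]
  } else {
    windows[, `:=`(age_band = NA_character_, sex = NA_character_)]
  }
  windows
}

# Person-time windows for the historical comparator.
historical_windows <- function(tables, window, variant, interval, seed) {
  op <- tables$observation_periods
  if (!variant$anchored) {
    w_start <- pmax(op$start_day, interval[1])
    w_end <- pmin(op$end_day, interval[2])
    keep <- w_end > w_start
    windows <- data.table::data.table(person_id = op$person_id[keep],
                                      w_start = w_start[keep], w_end = w_end[keep],
                                      index_day = w_start[keep])
  } else {
    vis <- tables$visits[visit_day >= interval[1] & visit_day < interval[2]]
    anchor <- if (nrow(vis) > 0L) {
      with_seed(seed, {
        v <- data.table::copy(vis)
        v[, r := stats::runif(.N)]
        data.table::setorder(v, person_id, r)
        unique(v, by = "person_id")[, .(person_id, visit_day)]
      })
    } else data.table::data.table(person_id = integer(), visit_day = integer())
    m <- merge(anchor, op, by = "person_id")
    w_start <- pmax(m$visit_day + window$start_offset, m$start_day)
    w_end <- pmin(m$visit_day + window$end_offset + 1L, m$end_day)
    keep <- w_end > w_start
    windows <- data.table::data.table(person_id = m$person_id[keep],
                                      w_start = w_start[keep], w_end = w_end[keep],
                                      index_day = m$visit_day[keep])
  }
  label_strata(windows, tables$persons, variant$adjusted)
}

# Person-time windows for the exposed cohort under accrual boundary `boundary`
# (half-open: data strictly before the boundary are visible).
observed_windows <- function(tables, vaccine_id, window, variant, boundary) {
  vid <- vaccine_id
  expo <- tables$exposures[vaccine_id == vid & exposure_day < boundary]
  m <- merge(expo, tables$observation_periods, by = "person_id")
  w_start <- pmax(m$exposure_day + window$start_offset, m$start_day)
  w_end <- pmin(m$exposure_day + window$end_offset + 1L, m$end_day, boundary)
  keep <- w_end > w_start
  windows <- data.table::data.table(person_id = m$person_id[keep],
                                    w_start = w_start[keep], w_end = w_end[keep],
                                    index_day = m$exposure_day[keep])
  label_strata(windows, tables$persons, variant$adjusted)
}

# Count first events per person within per-person half-open windows, then
# aggregate events and person-time by stratum.
rate_rows <- function(windows, events, oid) {
  if (nrow(windows) == 0L) {
    return(data.table::data.table(outcome_id = as.character(oid),
                                  age_band = NA_character_, sex = NA_character_,
                                  events = 0L, person_time = 0,
                                  rate = NA_real_, estimable = FALSE))
  }
  hit <- merge(windows[, .(person_id, w_start, w_end)], events,
               by = "person_id", allow.cartesian = TRUE)
  hit <- hit[outcome_day >= w_start & outcome_day < w_end]
  hit_ids <- if (nrow(hit)) unique(hit$person_id) else integer()
  out <- windows[, .(events = sum(person_id %in% hit_ids),
                     person_time = sum(w_end - w_start) / DAYS_PER_YEAR),
                 by = c("age_band", "sex")]
  out[, `:=`(outcome_id = as.character(oid),
             rate = ifelse(person_time > 0, events / person_time, NA_real_),
             estimable = person_time > 0)]
  data.table::setcolorder(out, c("outcome_id", "age_band", "sex", "events",
                                 "person_time", "rate", "estimable"))
  data.table::setorder(out, age_band, sex, na.last = TRUE)
  out[]
}

outcome_events <- function(tables, outcome_id) {
  oid <- as.character(outcome_id)  # force outside [ to avoid column masking
  tables$outcomes[list(oid), on = "outcome_id",
                  nomatch = NULL, .(person_id, outcome_day)]
}

#' Historical (background) incidence rates
#'
#' Unanchored designs use cohort-style person-time: each person's full time
#' in the historical interval, with their first outcome event in that
#' interval counted as incident. Anchored designs draw one outpatient visit
#' uniformly at random per person from their visits inside the interval
#' (persons without such a visit contribute nothing) and use the
#' time-at-risk window after that visit, clipped to the observation period.
#' Ages for stratification are taken at the index day (interval start for
#' unanchored person-time, anchor visit for anchored).
#'
#' @param tables an `event_tables`.
#' @param outcome_id outcome to tabulate.
#' @param window a [tar_window()] (used by anchored designs).
#' @param variant a [design_variant()].
#' @param historical_interval half-open day interval `c(start, end)`; default
#'   is the scenario's historical window.
#' @param seed integer seed for the random anchor visit (defaults to a value
#'   derived from the scenario seed, so repeated calls agree).
#' @return a `data.table` with one row per stratum (or one marginal row):
#'   `outcome_id, age_band, sex, events, person_time, rate, estimable`.
#' @export
historical_rates <- function(tables, outcome_id, window = tar_window(),
                             variant = design_variant(),
                             historical_interval = NULL, seed = NULL) {
  stopifnot(inherits(tables, "event_tables"), inherits(variant, "design_variant"))
  config <- attr(tables, "config")
  interval <- historical_interval %||% config$historical_window
  if (is.null(interval)) stop_config("historical_interval required when tables carry no config")
  seed <- seed %||% derive_seed((config$seed %||% 0L), 71L)
  windows <- historical_windows(tables, window, variant, interval, seed)
  rate_rows(windows, outcome_events(tables, outcome_id), outcome_id)
}

#' Observed (post-vaccination) incidence rates under monthly accrual
#'
#' Index is the vaccination day. Only exposures and outcome events recorded
#' before the end of accrual month `m` (30-day blocks from the start of the
#' surveillance window) are visible; the time-at-risk is clipped at the
#' accrual boundary and the observation-period end. First event per person
#' in the time-at-risk.
#'
#' @inheritParams historical_rates
#' @param vaccine_id the exposure of interest.
#' @param accrual_month data accumulated until the end of this month (1-based);
#'   defaults to the scenario's final month.
#' @return same shape as [historical_rates()].
#' @export
observed_rates <- function(tables, vaccine_id, outcome_id, window = tar_window(),
                           variant = design_variant(), accrual_month = NULL) {
  stopifnot(inherits(tables, "event_tables"))
  config <- attr(tables, "config")
  m <- accrual_month %||% config$n_months
  if (is.null(m) || m < 1) stop_config("accrual_month must be >= 1")
  surv_start <- if (!is.null(config)) config$surveillance_window[1] else 0L
  boundary <- surv_start + as.integer(m) * DAYS_PER_MONTH
  windows <- observed_windows(tables, vaccine_id, window, variant, boundary)
  ev <- outcome_events(tables, outcome_id)
  rate_rows(windows, ev[outcome_day < boundary], outcome_id)
}

#' Expected event count from background rates and observed person-time
#'
#' `E = sum over strata of background_rate_s * observed_person_time_s`.
#' Non-estimable when any stratum with positive observed person-time lacks an
#' estimable background rate, or when there is no observed person-time.
#'
#' @param background output of [historical_rates()].
#' @param observed output of [observed_rates()] (its `person_time` column is
#'   the per-stratum observed person-time).
#' @return list with `expected`, `estimable`, and `n_hist` (total historical
#'   events backing the expectation).
#' @export
expected_count <- function(background, observed) {
  n_hist <- sum(background$events)
  obs <- observed[person_time > 0]
  if (nrow(obs) == 0L)
    return(list(expected = NA_real_, estimable = FALSE, n_hist = n_hist))
  bg <- background[, .(age_band, sex, bg_rate = rate, bg_ok = estimable)]
  m <- merge(obs, bg, by = c("age_band", "sex"), all.x = TRUE)
  if (any(is.na(m$bg_rate) | !m$bg_ok))
    return(list(expected = NA_real_, estimable = FALSE, n_hist = n_hist))
  list(expected = sum(m$bg_rate * m$person_time), estimable = TRUE,
       n_hist = n_hist)
}
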