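# Control outcomes: negative controls pass through unchanged; positive
# controls are synthesized from them by injecting extra simulated events in
# the post-vaccination time-at-risk at a known true incidence rate ratio,
# with a constant hazard ratio over the window (default days 1-28).

#' Control definitions table
#'
#' @param control_id id of the control outcome.
#' @param parent_id the negative control it derives from (itself for
#'   negatives).
#' @param true_irr true incidence rate ratio (1.0 for negatives).
#' @return a `data.table` with columns `control_id, parent_id, true_irr,
#'   synthesized`.
#' @export
control_definition <- function(control_id, parent_id = control_id, true_irr = 1.0) {
  data.table::data.table(control_id = as.character(control_id),
                         parent_id = as.character(parent_id),
                         true_irr = as.numeric(true_irr),
                         synthesized = true_irr != 1.0)
}

# Exposed time-at-risk windows over the full study (no accrual clipping).
exposed_tar_windows <- function(tables, vaccine_id, window) {
  vid <- vaccine_id
  expo <- tables$exposures[vaccine_id == vid]
  m <- merge(expo, tables$observation_periods, by = "person_id")
  w_start <- pmax(m$exposure_day + window$start_offset, m$start_day)
  w_end <- pmin(m$exposure_day + window$end_offset + 1L, m$end_day)
  keep <- w_end > w_start
  data.table::data.table(person_id = m$person_id[keep],
                         w_start = w_start[keep], w_end = w_end[keep])
}

# First events per person within windows; marginal count and person-years.
count_first_events <- function(windows, events) {
  if (nrow(windows) == 0L) return(list(events = 0L, person_time = 0))
  hit <- merge(windows, events, by = "person_id", allow.cartesian = TRUE)
  hit <- hit[outcome_day >= w_start & outcome_day < w_end]
  n <- if (nrow(hit)) data.table::uniqueN(hit$person_id) else 0L
  list(events = n, person_time = sum(windows$w_end - windows$w_start) / DAYS_PER_YEAR)
}

#' Synthesize positive control outcomes by event injection
#'
#' For each negative control whose observed first-event count among exposed
#' time-at-risk windows reaches `min_outcomes`, and for each target IRR `r`,
#' a new outcome is created that copies all of the parent's occurrences and
#' adds, for each vaccinated person, extra events drawn from a homogeneous
#' process at rate `(r - 1) * lambda_hat` over the person's time-at-risk,
#' where `lambda_hat` is the parent's marginal first-event rate among exposed
#' time-at-risk person-time. This preserves the target marginal IRR in
#' expectation with a constant hazard ratio across the window. Parents below
#' the threshold produce no positives.
#'
#' @param tables an `event_tables`.
#' @param vaccine_id exposure of interest.
#' @param negative_ids character vector of negative-control outcome ids.
#' @param window the post-vaccination [tar_window()].
#' @param irrs target true incidence rate ratios, all > 1.
#' @param min_outcomes minimum parent first-event count among exposed
#'   time-at-risk windows for synthesis (default 25).
#' @param seed integer seed for the injection draws.
#' @return list with `tables` (outcomes augmented), `controls` (definitions
#'   for negatives and created positives) and `manifest` (per positive:
#'   parent, true_irr, injected event count, parent event count).
#' @export
synthesize_positive_controls <- function(tables, vaccine_id, negative_ids,
                                         window = tar_window(),
                                         irrs = c(1.5, 2, 4),
                                         min_outcomes = 25L, seed = 1L) {
  stopifnot(inherits(tables, "event_tables"))
  if (min_outcomes <= 0) stop_config("min_outcomes must be a positive count")
  if (any(irrs <= 1)) stop_config("target IRRs must all be > 1")
  negative_ids <- as.character(negative_ids)
  missing_ids <- setdiff(negative_ids, unique(tables$outcomes$outcome_id))
  # ids with zero events are permitted (they simply fail the threshold), but
  # they must at least be declared outcomes of the scenario
  config <- attr(tables, "config")
  unknown <- if (!is.null(config) && length(config$outcome_defs)) {
    declared <- vapply(config$outcome_defs, function(d) as.character(d$outcome_id), "")
    setdiff(missing_ids, declared)
  } else missing_ids
  if (length(unknown))
    stop_config("negative ids not present in outcomes: %s",
                paste(unknown, collapse = ", "))

  windows <- exposed_tar_windows(tables, vaccine_id, window)
  controls <- control_definition(negative_ids)
  manifest_rows <- list()
  new_rows <- list()

  with_seed(seed, {
    for (nid in negative_ids) {
      ev <- tables$outcomes[list(nid), on = "outcome_id", nomatch = NULL,
                            .(person_id, outcome_day)]
      cnt <- count_first_events(windows, ev)
      if (cnt$events < min_outcomes || cnt$person_time <= 0) next
      lambda_hat <- cnt$events / cnt$person_time
      for (r in irrs) {
        cid <- sprintf("%s_irr%g", nid, r)
        len_days <- windows$w_end - windows$w_start
        n_extra <- stats::rpois(nrow(windows),
                                (r - 1) * lambda_hat * len_days / DAYS_PER_YEAR)
        idx <- rep.int(seq_len(nrow(windows)), n_extra)
        inj_day <- windows$w_start[idx] +
          as.integer(floor(stats::runif(length(idx)) * len_days[idx]))
        copied <- if (nrow(ev)) data.table::data.table(
          person_id = ev$person_id, outcome_id = cid, outcome_day = ev$outcome_day)
        else NULL
        injected <- if (length(idx)) data.table::data.table(
          person_id = windows$person_id[idx], outcome_id = cid, outcome_day = inj_day)
        else NULL
        new_rows[[cid]] <- rbind(copied, injected)
        controls <- rbind(controls, control_definition(cid, nid, r))
        manifest_rows[[cid]] <- data.table::data.table(
          control_id = cid, parent_id = nid, true_irr = r,
          injected_count = length(idx), parent_tar_events = cnt$events,
          parent_tar_rate = lambda_hat)
      }
    }
  })

  if (length(new_rows)) {
    out <- rbind(tables$outcomes, data.table::rbindlist(new_rows))
    data.table::setorder(out, outcome_id, person_id, outcome_day)
    tables$outcomes <- out
  }
  manifest <- if (length(manifest_rows)) data.table::rbindlist(manifest_rows)
  else data.table::data.table(control_id = character(), parent_id = character(),
                              true_irr = numeric(), injected_count = integer(),
                              parent_tar_events = integer(), parent_tar_rate = numeric())
  list(tables = tables, controls = controls, manifest = manifest)
}

#' Realized marginal IRR of a synthesized control
#'
#' Ratio of the post-injection exposed time-at-risk first-event rate of the
#' control to the pre-injection rate of its parent. In expectation this
#' equals the target true IRR (up to first-event truncation, negligible at
#' realistic event rates).
#'
#' @param tables `event_tables` after injection.
#' @param control_id the synthesized control's outcome id.
#' @param parent_id its parent negative control.
#' @param vaccine_id exposure of interest.
#' @param window the [tar_window()] used at synthesis.
#' @return the realized IRR (`NA` with a warning if the parent has no events).
#' @export
realized_irr <- function(tables, control_id, parent_id, vaccine_id,
                         window = tar_window()) {
  windows <- exposed_tar_windows(tables, vaccine_id, window)
  ev_post <- tables$outcomes[list(as.character(control_id)), on = "outcome_id",
                             nomatch = NULL, .(person_id, outcome_day)]
  ev_pre <- tables$outcomes[list(as.character(parent_id)), on = "outcome_id",
                            nomatch = NULL, .(person_id, outcome_day)]
  post <- count_first_events(windows, ev_post)
  pre <- count_first_events(windows, ev_pre)
  if (pre$events == 0L) {
    warning("parent has no exposed time-at-risk events; realized IRR not estimable")
    return(NA_real_)
  }
  (post$events / post$person_time) / (pre$events / pre$person_time)
}
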