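# Effect estimation for one (control, design, accrual month) cell:
# IRR = O / E with O the observed post-vaccination first-event count and E
# the expected count projected from background rates. The exact one-sided
# Poisson tail p-value treats E as fixed (conditional test); historical
# sampling error enters the confidence interval through the standard error.

#' Exact one-sided Poisson tail probability
#'
#' `P(X >= O)` for `X ~ Poisson(E)`: the elevated-risk tail used for signal
#' detection.
#'
#' @param observed event count(s) `O`.
#' @param expected expected count(s) `E > 0`.
#' @return p-value(s) in `[0, 1]`.
#' @export
poisson_tail_p <- function(observed, expected) {
  stopifnot(all(expected > 0), all(observed >= 0))
  stats::ppois(observed - 1, expected, lower.tail = FALSE)
}

#' One-sided Poisson log likelihood ratio (MaxSPRT statistic)
#'
#' `LLR = O * ln(O/E) - (O - E)` when `O > E`, else 0.
#'
#' @inheritParams poisson_tail_p
#' @return non-negative LLR value(s).
#' @export
poisson_llr <- function(observed, expected) {
  stopifnot(all(expected > 0), all(observed >= 0))
  llr <- ifelse(observed > expected,
                observed * log(observed / expected) - (observed - expected), 0)
  pmax(llr, 0)
}

#' Core effect estimate from observed and expected counts
#'
#' `IRR = O/E`, `se(log IRR) = sqrt(1/O + 1/n_hist)` with `n_hist` the
#' historical event count behind `E`, Wald 95% CI on the log scale, the exact
#' one-sided Poisson p and the MaxSPRT LLR. Cells with `O = 0`, `E` missing
#' or zero, or `n_hist = 0` are flagged non-estimable with all statistics
#' `NA`.
#'
#' @param observed observed event count `O`.
#' @param expected expected event count `E`.
#' @param n_hist historical event count used to estimate the background rate.
#' @return one-row `data.table` with columns `observed, expected, n_hist,
#'   log_irr, se_log_irr, ci_low, ci_high, p, llr, estimable`.
#' @export
estimate_effect <- function(observed, expected, n_hist) {
  not_est <- data.table::data.table(
    observed = as.integer(observed %||% NA),
    expected = as.numeric(expected %||% NA), n_hist = as.integer(n_hist %||% NA),
    log_irr = NA_real_, se_log_irr = NA_real_, ci_low = NA_real_,
    ci_high = NA_real_, p = NA_real_, llr = NA_real_, estimable = FALSE)
  if (is.null(expected) || is.na(expected) || expected <= 0 ||
      is.na(observed) || observed <= 0 || is.na(n_hist) || n_hist < 1)
    return(not_est)
  log_irr <- log(observed / expected)
  se <- sqrt(1 / observed + 1 / n_hist)
  data.table::data.table(
    observed = as.integer(observed), expected = as.numeric(expected),
    n_hist = as.integer(n_hist), log_irr = log_irr, se_log_irr = se,
    ci_low = exp(log_irr - 1.96 * se), ci_high = exp(log_irr + 1.96 * se),
    p = poisson_tail_p(observed, expected),
    llr = poisson_llr(observed, expected), estimable = TRUE)
}

#' Estimate all (control, design, month) cells for a scenario
#'
#' Background rates are computed once per (control, design); observed rates
#' are recomputed per accrual month. Non-estimable cells (no exposed persons
#' yet, zero expected, zero observed) are emitted flagged, never dropped.
#'
#' @param tables `event_tables` (after any control synthesis).
#' @param controls control-definitions table (see [control_definition()]).
#' @param vaccine_id exposure of interest.
#' @param window the post-vaccination [tar_window()].
#' @param designs list of [design_variant()]s (default all four).
#' @param months accrual months to evaluate (default only the final month).
#' @return a `data.table`: one row per control x design x month with the
#'   [estimate_effect()] columns plus `control_id, parent_id, true_irr,
#'   design, month`.
#' @export
estimate_controls <- function(tables, controls, vaccine_id,
                              window = tar_window(),
                              designs = design_grid(), months = NULL) {
  config <- attr(tables, "config")
  if (is.null(config)) stop_config("estimate_controls needs tables carrying a scenario_config")
  months <- as.integer(months %||% config$n_months)
  interval <- config$historical_window
  anchor_seed <- derive_seed(config$seed, 71L)
  surv_start <- config$surveillance_window[1]

  rows <- list()
  k <- 1L
  for (variant in designs) {
    # person-time windows are outcome-independent: compute once per design
    hw <- historical_windows(tables, window, variant, interval, anchor_seed)
    ow <- lapply(months, function(m)
      observed_windows(tables, vaccine_id, window, variant,
                       surv_start + m * DAYS_PER_MONTH))
    for (i in seq_len(nrow(controls))) {
      cid <- controls$control_id[i]
      ev <- outcome_events(tables, cid)
      bg <- rate_rows(hw, ev, cid)
      for (mi in seq_along(months)) {
        m <- months[mi]
        boundary <- surv_start + m * DAYS_PER_MONTH
        obs <- rate_rows(ow[[mi]], ev[outcome_day < boundary], cid)
        ec <- expected_count(bg, obs)
        est <- estimate_effect(sum(obs$events),
                               if (ec$estimable) ec$expected else NA_real_,
                               ec$n_hist)
        rows[[k]] <- data.table::data.table(
          control_id = cid, parent_id = controls$parent_id[i],
          true_irr = controls$true_irr[i], design = variant$label,
          month = m, est)
        k <- k + 1L
      }
    }
  }
  data.table::rbindlist(rows)
}
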