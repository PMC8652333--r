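# Performance metrics over control estimates: bias (type 1/2 error, AUC,
# coverage), precision (geometric mean precision, MSE), estimability
# filtering, and timeliness under monthly accrual. The signal rule is
# one-sided p < 0.05 throughout; a positive control is "missed" when its p
# is not below the threshold.

#' Type 1 error
#'
#' Fraction of negative-control p-values below `alpha`.
#'
#' @param p p-values of estimable negative controls.
#' @param alpha signal threshold (default 0.05).
#' @return proportion in `[0,1]`, `NA` if no finite p-values.
#' @export
type1_error <- function(p, alpha = 0.05) {
  p <- p[is.finite(p)]
  if (!length(p)) return(NA_real_)
  mean(p < alpha)
}

#' Type 2 error
#'
#' Fraction of positive-control p-values not below `alpha` (missed signals),
#' overall or per true IRR.
#'
#' @param p p-values of estimable positive controls.
#' @param true_irr optional vector of true IRRs, required for `by_irr`.
#' @param by_irr report per true IRR instead of overall?
#' @param alpha signal threshold.
#' @return a proportion, or a `data.table(true_irr, type2)` when `by_irr`.
#' @export
type2_error <- function(p, true_irr = NULL, by_irr = FALSE, alpha = 0.05) {
  ok <- is.finite(p)
  if (!by_irr) {
    if (!any(ok)) return(NA_real_)
    return(mean(p[ok] >= alpha))
  }
  stopifnot(!is.null(true_irr))
  dt <- data.table::data.table(p = p[ok], true_irr = true_irr[ok])
  dt[, .(type2 = mean(p >= alpha)), keyby = true_irr]
}

#' Rank-based AUC discriminating positive from negative controls
#'
#' Mann-Whitney AUC with ties counted one half, using the effect estimate
#' (log IRR) as the score.
#'
#' @param neg_scores scores of negative controls.
#' @param pos_scores scores of positive controls.
#' @return AUC in `[0,1]`, `NA` if either class is empty.
#' @export
auc_controls <- function(neg_scores, pos_scores) {
  neg_scores <- neg_scores[is.finite(neg_scores)]
  pos_scores <- pos_scores[is.finite(pos_scores)]
  n0 <- length(neg_scores); n1 <- length(pos_scores)
  if (n0 == 0L || n1 == 0L) return(NA_real_)
  r <- rank(c(pos_scores, neg_scores), ties.method = "average")
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Confidence interval coverage of the true IRR
#'
#' @param ci_low,ci_high 95% CI bounds on the IRR scale.
#' @param true_irr the controls' true IRRs.
#' @return fraction of intervals containing the truth.
#' @export
coverage <- function(ci_low, ci_high, true_irr) {
  ok <- !is.na(ci_low) & !is.na(ci_high)  # infinite bounds are legitimate
  if (!any(ok)) return(NA_real_)
  mean(true_irr[ok] >= ci_low[ok] & true_irr[ok] <= ci_high[ok])
}

#' Geometric mean precision and mean squared error
#'
#' Precision of one estimate is `1 / se^2`; the summary is its geometric
#' mean. MSE is the mean squared difference between estimated and true log
#' IRR.
#'
#' @param log_irr estimated log IRRs.
#' @param se standard errors.
#' @param true_irr true IRRs.
#' @return list with `mean_precision` and `mse`.
#' @export
precision_and_mse <- function(log_irr, se, true_irr) {
  ok <- is.finite(log_irr) & is.finite(se) & se > 0
  if (!any(ok)) return(list(mean_precision = NA_real_, mse = NA_real_))
  list(mean_precision = exp(mean(log(1 / se[ok]^2))),
       mse = mean((log_irr[ok] - log(true_irr[ok]))^2))
}

#' Monthly population incidence rates over the surveillance window
#'
#' All-event counts divided by population person-time in each 30-day
#' surveillance month; the series feeds the rate-stability exclusion rule.
#'
#' @param tables an `event_tables`.
#' @param outcome_ids outcomes to tabulate (default: every id in the table).
#' @return `data.table(outcome_id, month, rate)`.
#' @export
monthly_population_rates <- function(tables, outcome_ids = NULL) {
  config <- attr(tables, "config")
  if (is.null(config)) stop_config("tables must carry a scenario_config")
  surv <- config$surveillance_window
  op <- tables$observation_periods
  ids <- as.character(outcome_ids %||% unique(tables$outcomes$outcome_id))
  months <- seq_len(config$n_months)
  pt <- vapply(months, function(m) {
    lo <- surv[1] + (m - 1L) * DAYS_PER_MONTH
    hi <- lo + DAYS_PER_MONTH
    sum(overlap_days(op$start_day, op$end_day, lo, hi)) / DAYS_PER_YEAR
  }, 0)
  ev <- tables$outcomes[outcome_id %in% ids &
                          outcome_day >= surv[1] & outcome_day < surv[2]]
  ev[, month := (outcome_day - surv[1]) %/% DAYS_PER_MONTH + 1L]
  grid <- data.table::CJ(outcome_id = ids, month = months)
  cnt <- ev[, .N, by = .(outcome_id, month)]
  out <- merge(grid, cnt, by = c("outcome_id", "month"), all.x = TRUE)
  out[is.na(N), N := 0L]
  out[, rate := N / pt[month]][, N := NULL]
  out[]
}

#' Estimability filter
#'
#' Flags and drops (a) estimates already non-estimable (no exposed persons,
#' zero expected or zero observed events) and (b) all rows of negative
#' controls whose monthly population incidence changes by more than 50% over
#' the surveillance period, read as `max/min > 1.5` across months with
#' non-zero rates.
#'
#' @param estimates output of [estimate_controls()].
#' @param rate_series output of [monthly_population_rates()] for the parent
#'   outcomes.
#' @param threshold ratio threshold (default 1.5).
#' @return list with `estimates` (retained rows) and `exclusions`
#'   (`data.table(control_id, design, month, reason)`).
#' @export
estimability_filter <- function(estimates, rate_series, threshold = 1.5) {
  stability <- rate_series[rate > 0,
                           .(ratio = max(rate) / min(rate)), by = outcome_id]
  unstable <- stability[ratio > threshold, outcome_id]
  excl_rate <- estimates[true_irr == 1 & control_id %in% unstable,
                         .(control_id, design, month, reason = "rate_change")]
  excl_nonest <- estimates[estimable == FALSE,
                           .(control_id, design, month, reason = "not_estimable")]
  drop_key <- paste(excl_rate$control_id, excl_rate$design, excl_rate$month)
  ne_key <- paste(excl_nonest$control_id, excl_nonest$design, excl_nonest$month)
  keys <- paste(estimates$control_id, estimates$design, estimates$month)
  keep <- !(keys %in% c(drop_key, ne_key))
  list(estimates = estimates[keep],
       exclusions = rbind(excl_rate, excl_nonest))
}

#' Metrics table: one row per (design, month)
#'
#' Computes every performance metric on a control estimates table, either on
#' the uncalibrated exact-Poisson side or on the calibrated side.
#'
#' @param estimates output of [estimate_controls()] (optionally after
#'   [leave_one_out_calibrate()] and/or [estimability_filter()]).
#' @param calibrated use calibrated p/CI/estimates (requires calibration
#'   columns)?
#' @param alpha signal threshold.
#' @return a `data.table` with one row per design x month carrying `type1`,
#'   `type2`, per-IRR type 2 columns, `auc`, `coverage`, `mean_precision`,
#'   `mse`, estimable-control counts and the non-estimable fraction.
#' @export
metrics_table <- function(estimates, calibrated = FALSE, alpha = 0.05) {
  est <- data.table::copy(estimates)
  if (calibrated) {
    if (!"cal_p" %in% names(est))
      stop_config("estimates carry no calibration columns; run leave_one_out_calibrate first")
    est[, `:=`(use_p = cal_p, use_log_irr = cal_log_irr, use_se = cal_se,
               use_lo = cal_ci_low, use_hi = cal_ci_high,
               usable = estimable & calibrated)]
  } else {
    est[, `:=`(use_p = p, use_log_irr = log_irr, use_se = se_log_irr,
               use_lo = ci_low, use_hi = ci_high, usable = estimable)]
  }
  cal_flag <- isTRUE(calibrated)
  est[, .(
    calibrated = cal_flag,
    type1 = type1_error(use_p[usable & true_irr == 1], alpha),
    type2 = type2_error(use_p[usable & true_irr > 1], alpha = alpha),
    auc = auc_controls(use_log_irr[usable & true_irr == 1],
                       use_log_irr[usable & true_irr > 1]),
    coverage = coverage(use_lo[usable], use_hi[usable], true_irr[usable]),
    mean_precision = precision_and_mse(use_log_irr[usable], use_se[usable],
                                       true_irr[usable])$mean_precision,
    mse = precision_and_mse(use_log_irr[usable], use_se[usable],
                            true_irr[usable])$mse,
    n_negatives_estimable = sum(usable & true_irr == 1),
    n_positives_estimable = sum(usable & true_irr > 1),
    fraction_not_estimable = mean(!usable),
    type2_by_irr = list(type2_error(use_p[usable & true_irr > 1],
                                    true_irr[usable & true_irr > 1],
                                    by_irr = TRUE, alpha = alpha))
  ), keyby = .(design, month)]
}

#' Timeliness: first detection month per positive control
#'
#' For each positive control and design, the earliest accrual month at which
#' the (calibrated or uncalibrated) one-sided p falls below `alpha`; `NA`
#' when never detected within the evaluated months.
#'
#' @inheritParams metrics_table
#' @return `data.table(control_id, parent_id, true_irr, design,
#'   first_detection_month)`.
#' @export
timeliness_table <- function(estimates, calibrated = FALSE, alpha = 0.05) {
  est <- data.table::copy(estimates)
  if (calibrated) est[, use_p := cal_p] else est[, use_p := p]
  pos <- est[true_irr > 1]
  pos[, detected := estimable & is.finite(use_p) & use_p < alpha]
  pos[, .(first_detection_month =
            if (any(detected)) min(month[detected]) else NA_integer_),
      keyby = .(control_id, parent_id, true_irr, design)]
}
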