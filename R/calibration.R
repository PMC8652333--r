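# Empirical calibration.
#
# Control estimates carry known truths (log IRR 0 for negatives, log of the
# injected IRR for positives). Subtracting each control's truth from its
# estimate gives a bias observation, modelled as Gaussian systematic error
# convolved with the estimate's Gaussian sampling error:
#   bias_i ~ N(mu, sigma^2 + se_i^2).
# The systematic error is assumed constant across true effect sizes, which
# licenses pooling negatives and positives in one fit. Calibrated p-values
# and intervals then widen by sigma and shift by mu; leave-one-out excludes
# the control being calibrated (and, by default, its whole parent family)
# from the fit.

#' Fit the systematic error distribution
#'
#' Maximum likelihood for `(mu, sigma)` in the convolution model
#' `log_irr_i - true_log_irr_i ~ N(mu, sigma^2 + se_i^2)`, via bounded
#' quasi-Newton on `(mu, log sigma)` with multiple starts.
#'
#' @param log_irr estimated log IRRs.
#' @param se their standard errors.
#' @param true_log_irr known true log IRRs (default all 0, i.e. negative
#'   controls only).
#' @return a `systematic_error_model`: list with `mu`, `sigma`, `n_fitted`,
#'   `converged`.
#' @export
fit_systematic_error <- function(log_irr, se, true_log_irr = 0) {
  ok <- is.finite(log_irr) & is.finite(se) & se >= 0
  bias <- (log_irr - true_log_irr)[ok]
  se <- se[ok]
  if (length(bias) < 2L)
    return(structure(list(mu = NA_real_, sigma = NA_real_,
                          n_fitted = length(bias), converged = FALSE),
                     class = "systematic_error_model"))
  negll <- function(par) {
    s2 <- exp(2 * par[2]) + se^2
    0.5 * sum(log(2 * pi * s2) + (bias - par[1])^2 / s2)
  }
  mad0 <- stats::mad(bias)
  starts <- list(c(0, -2), c(0, 0),
                 c(stats::median(bias), log(max(mad0, 1e-3))))
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(s, negll, method = "L-BFGS-B",
                   lower = c(-10, -12), upper = c(10, 5),
                   control = list(factr = 1e-8 / .Machine$double.eps)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value - 1e-12) best <- fit
  }
  if (is.null(best))
    return(structure(list(mu = NA_real_, sigma = NA_real_,
                          n_fitted = length(bias), converged = FALSE),
                     class = "systematic_error_model"))
  structure(list(mu = best$par[1], sigma = exp(best$par[2]),
                 n_fitted = length(bias), converged = best$convergence == 0),
            class = "systematic_error_model")
}

#' @export
print.systematic_error_model <- function(x, ...) {
  cat(sprintf("<systematic_error_model> mu=%.4f sigma=%.4f (n=%d, %s)\n",
              x$mu, x$sigma, x$n_fitted,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Calibrate effect estimates against a systematic error model
#'
#' Shifts the point estimate by `mu`, inflates the standard error to
#' `sqrt(se^2 + sigma^2)`, and recomputes the 95% CI and the one-sided
#' p-value for elevated risk:
#' `p_cal = 1 - Phi((log_irr - mu) / sqrt(se^2 + sigma^2))`.
#'
#' @param log_irr estimated log IRR(s).
#' @param se standard error(s).
#' @param model a converged `systematic_error_model`.
#' @return `data.table` with `cal_log_irr, cal_se, cal_ci_low, cal_ci_high,
#'   cal_p` (all `NA` if the model did not converge).
#' @export
calibrate_estimate <- function(log_irr, se, model) {
  n <- length(log_irr)
  if (!isTRUE(model$converged)) {
    return(data.table::data.table(cal_log_irr = rep(NA_real_, n),
                                  cal_se = NA_real_, cal_ci_low = NA_real_,
                                  cal_ci_high = NA_real_, cal_p = NA_real_))
  }
  cal_log_irr <- log_irr - model$mu
  cal_se <- sqrt(se^2 + model$sigma^2)
  data.table::data.table(
    cal_log_irr = cal_log_irr, cal_se = cal_se,
    cal_ci_low = exp(cal_log_irr - 1.96 * cal_se),
    cal_ci_high = exp(cal_log_irr + 1.96 * cal_se),
    cal_p = stats::pnorm(cal_log_irr / cal_se, lower.tail = FALSE))
}

#' Leave-one-out calibration of a control estimates table
#'
#' Within every (design, month) cell, each control's estimate is calibrated
#' with a systematic error model fitted on all other estimable controls in
#' that cell. With `loo_family = TRUE` (default) the exclusion extends to
#' the held-out control's parent negative control and all positives sharing
#' that parent, since those share the parent's events; `FALSE` gives the
#' literal exclude-only-self behaviour.
#'
#' @param estimates output of [estimate_controls()].
#' @param loo_family exclude the whole parent family of the held-out
#'   control?
#' @return `estimates` with calibration columns added (`cal_log_irr`,
#'   `cal_se`, `cal_ci_low`, `cal_ci_high`, `cal_p`, `cal_mu`, `cal_sigma`,
#'   `calibrated` flag; `calibrated = FALSE` rows keep `NA` calibrated
#'   fields).
#' @export
leave_one_out_calibrate <- function(estimates, loo_family = TRUE) {
  est <- data.table::copy(estimates)
  est[, `:=`(cal_log_irr = NA_real_, cal_se = NA_real_, cal_ci_low = NA_real_,
             cal_ci_high = NA_real_, cal_p = NA_real_, cal_mu = NA_real_,
             cal_sigma = NA_real_, calibrated = FALSE)]
  groups <- unique(est[, .(design, month)])
  for (g in seq_len(nrow(groups))) {
    rows <- which(est$design == groups$design[g] & est$month == groups$month[g])
    cell <- est[rows]  # static snapshot; calibrated fields never enter fits
    if (sum(cell$estimable) < 3L) next
    for (i in which(cell$estimable)) {
      fam <- if (loo_family) cell$parent_id == cell$parent_id[i]
      else cell$control_id == cell$control_id[i]
      pool <- cell[estimable & !fam]
      if (nrow(pool) < 2L) next
      model <- fit_systematic_error(pool$log_irr, pool$se_log_irr,
                                    log(pool$true_irr))
      if (!model$converged) next
      cal <- calibrate_estimate(cell$log_irr[i], cell$se_log_irr[i], model)
      est[rows[i], `:=`(cal_log_irr = cal$cal_log_irr, cal_se = cal$cal_se,
                        cal_ci_low = cal$cal_ci_low,
                        cal_ci_high = cal$cal_ci_high,
                        cal_p = cal$cal_p, cal_mu = model$mu,
                        cal_sigma = model$sigma, calibrated = TRUE)]
    }
  }
  est
}
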