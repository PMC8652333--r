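# Systematic error model: MLE fitting, closed-form calibration, leave-one-out.

test_that("symmetric two-estimate fit centres at zero bias", {
  m <- fit_systematic_error(c(-0.2, 0.2), c(0.1, 0.1))
  expect_true(m$converged)
  expect_equal(m$mu, 0, tolerance = 1e-4)
})

test_that("degenerate fits are flagged", {
  m <- fit_systematic_error(0.3, 0.1)
  expect_false(m$converged)
  expect_true(is.na(m$mu))
})

test_that("MLE recovers a known bias distribution", {
  set.seed(91)
  n <- 500
  se <- runif(n, 0.05, 0.2)
  bias <- rnorm(n, 0.2, 0.1)
  est <- bias + rnorm(n, 0, se)
  m <- fit_systematic_error(est, se)
  # 3-SE recovery bands (SEs approximated from the Fisher information of a
  # Gaussian mean/SD with n observations)
  expect_lt(abs(m$mu - 0.2), 3 * sqrt((0.1^2 + mean(se)^2) / n))
  expect_lt(abs(m$sigma - 0.1), 3 * 0.15 / sqrt(n))
})

test_that("positives enter the fit through truth subtraction", {
  set.seed(92)
  truths <- rep(c(0, log(2)), each = 50)
  se <- rep(0.1, 100)
  est <- truths + 0.25 + rnorm(100, 0, se)  # constant bias 0.25, sigma ~ 0
  m <- fit_systematic_error(est, se, truths)
  expect_equal(m$mu, 0.25, tolerance = 0.05)
  expect_lt(m$sigma, 0.1)
})

test_that("calibration closed form: identity, monotonicity, quadrature oracle", {
  id_model <- structure(list(mu = 0, sigma = 0, n_fitted = 10, converged = TRUE),
                        class = "systematic_error_model")
  cal <- calibrate_estimate(0.3, 0.15, id_model)
  expect_equal(cal$cal_p, pnorm(0.3 / 0.15, lower.tail = FALSE))
  expect_equal(cal$cal_log_irr, 0.3)
  expect_equal(cal$cal_ci_low, exp(0.3 - 1.96 * 0.15))

  shift_model <- structure(list(mu = 0.2, sigma = 0, n_fitted = 10, converged = TRUE),
                           class = "systematic_error_model")
  expect_gt(calibrate_estimate(0.3, 0.15, shift_model)$cal_p, cal$cal_p)

  # oracle: numerical integration over the bias distribution of
  # P(estimate >= observed | true log IRR = 0, bias ~ N(mu, sigma^2))
  cases <- data.frame(log_irr = c(0.5, 0.1, -0.2, 0.8, 0.3),
                      se = c(0.1, 0.2, 0.15, 0.3, 0.05),
                      mu = c(0.2, 0.0, -0.1, 0.3, 0.25),
                      sigma = c(0.1, 0.15, 0.05, 0.2, 0.1))
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    model <- structure(list(mu = cs$mu, sigma = cs$sigma, n_fitted = 10,
                            converged = TRUE), class = "systematic_error_model")
    closed <- calibrate_estimate(cs$log_irr, cs$se, model)$cal_p
    quad <- integrate(function(b)
      dnorm(b, cs$mu, cs$sigma) * pnorm((cs$log_irr - b) / cs$se, lower.tail = FALSE),
      cs$mu - 8 * cs$sigma, cs$mu + 8 * cs$sigma, rel.tol = 1e-10)$value
    expect_equal(closed, quad, tolerance = 1e-4)
  }

  # non-converged models pass through with NA calibrated fields
  bad <- structure(list(mu = NA, sigma = NA, converged = FALSE),
                   class = "systematic_error_model")
  expect_true(all(is.na(calibrate_estimate(0.3, 0.15, bad))))
})

make_estimates <- function(log_irr, se, true_irr = rep(1, length(log_irr)),
                           parent = NULL) {
  n <- length(log_irr)
  data.table::data.table(
    control_id = sprintf("c%02d", seq_len(n)),
    parent_id = parent %||% sprintf("c%02d", seq_len(n)),
    true_irr = true_irr, design = "unadjusted", month = 9L,
    observed = 10L, expected = 10, n_hist = 100L,
    log_irr = log_irr, se_log_irr = se,
    ci_low = exp(log_irr - 1.96 * se), ci_high = exp(log_irr + 1.96 * se),
    p = pnorm(log_irr / se, lower.tail = FALSE),
    llr = 0, estimable = TRUE)
}

test_that("leave-one-out: bookkeeping and the three-identical-controls identity", {
  est <- make_estimates(c(0.1, 0.1, 0.1), c(0.2, 0.2, 0.2))
  out <- leave_one_out_calibrate(est)
  expect_equal(nrow(out), 3L)
  expect_true(all(out$calibrated))
  # each LOO model is fitted on the two identical others
  ref <- fit_systematic_error(c(0.1, 0.1), c(0.2, 0.2))
  expect_equal(out$cal_mu, rep(ref$mu, 3), tolerance = 1e-5)
  expect_equal(out$cal_sigma, rep(ref$sigma, 3), tolerance = 1e-4)
})

test_that("leave-one-out excludes the held-out family and reacts to extremes", {
  set.seed(93)
  n <- 30
  est <- make_estimates(rnorm(n, 0.1, 0.05), rep(0.1, n))
  est$log_irr[1] <- 2.5  # one extreme-bias control
  out <- leave_one_out_calibrate(est)
  full <- fit_systematic_error(est$log_irr, est$se_log_irr)
  cal_full <- calibrate_estimate(est$log_irr[1], est$se_log_irr[1], full)
  # removing the extreme control changes its own calibrated p: without
  # self-influence the outlier is less explained away, so p drops
  expect_lt(out$cal_p[1], cal_full$cal_p)
  expect_equal(sum(out$control_id == "c01"), 1L)

  # family exclusion: positives sharing the held-out parent leave the pool
  fam <- make_estimates(c(0, 0, 0, 0.7, 0.7), rep(0.1, 5),
                        true_irr = c(1, 1, 1, 2, 2),
                        parent = c("p1", "p2", "p3", "p1", "p1"))
  out_fam <- leave_one_out_calibrate(fam, loo_family = TRUE)
  out_self <- leave_one_out_calibrate(fam, loo_family = FALSE)
  # for the p1 negative, family LOO drops rows 4 and 5 as well -> different model
  expect_false(isTRUE(all.equal(out_fam$cal_mu[1], out_self$cal_mu[1])))
})

test_that("calibration reduces precision whenever sigma is positive", {
  set.seed(94)
  est <- make_estimates(rnorm(40, 0.3, 0.25), runif(40, 0.05, 0.15))
  out <- leave_one_out_calibrate(est)
  done <- out[calibrated == TRUE & cal_sigma > 0]
  expect_gt(nrow(done), 0)
  expect_true(all(1 / done$cal_se^2 < 1 / done$se_log_irr^2))
})
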