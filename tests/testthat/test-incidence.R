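# Incidence computation: historical and observed rates under the four
# designs, expected counts, accrual semantics.

test_that("five-person fixture reproduces the hand tally", {
  fx <- load_fixture("five_person_rates")
  r <- historical_rates(fx$tables, "oc", variant = design_variant(),
                        historical_interval = fx$historical_interval, seed = 1L)
  expect_equal(r$events, fx$expected$events)
  expect_equal(r$person_time, fx$expected$person_time)
  expect_equal(r$rate, fx$expected$rate)
})

test_that("anchored historical rates: persons without visits contribute nothing", {
  tabs <- load_fixture("five_person_rates")$tables
  # one visit for person 1 only, inside the interval; time-at-risk is
  # [-209, -181), which contains person 1's event on day -200
  tabs$visits <- data.table::data.table(person_id = 1L, visit_day = -210L)
  r <- historical_rates(tabs, "oc", variant = design_variant(anchored = TRUE),
                        historical_interval = c(-365L, -95L), seed = 1L)
  expect_equal(r$person_time, 28 / 365.25)  # person 1's 28-day window only
  expect_equal(r$events, 1L)
})

test_that("stratified historical counts equal a brute-force per-person tally", {
  cfg <- scenario_config(n_persons = 300L, outcome_defs = make_negatives(1, 0.5, 0.5),
                         seed = 21L)
  tabs <- simulate_scenario(cfg)
  variant <- design_variant(adjusted = TRUE)
  got <- historical_rates(tabs, "nc001", variant = variant)

  # oracle: exhaustive per-person loop in base R
  hw <- cfg$historical_window
  pers <- as.data.frame(tabs$persons)
  ev <- as.data.frame(tabs$outcomes)
  tally <- list()
  for (i in seq_len(nrow(pers))) {
    p <- pers[i, ]
    band <- age_band_label(age_band((hw[1] - p$birth_day) / 365.25))
    key <- paste(band, p$sex)
    e <- ev[ev$person_id == p$person_id &
              ev$outcome_day >= hw[1] & ev$outcome_day < hw[2], ]
    rec <- tally[[key]] %||% c(events = 0, pt = 0)
    rec["events"] <- rec["events"] + (nrow(e) > 0)
    rec["pt"] <- rec["pt"] + (hw[2] - hw[1]) / 365.25
    tally[[key]] <- rec
  }
  for (i in seq_len(nrow(got))) {
    key <- paste(got$age_band[i], got$sex[i])
    expect_equal(unname(tally[[key]]["events"]), as.numeric(got$events[i]),
                 info = key)
    expect_equal(unname(tally[[key]]["pt"]), got$person_time[i], info = key)
  }
  expect_equal(length(tally), nrow(got))
})

test_that("observed rates follow the arithmetic and accrual contracts", {
  # 100 vaccinees with full 28-day windows and 4 events
  n <- 100L
  tabs <- oebench:::make_event_tables(
    persons = data.frame(person_id = 1:n, sex = "F", birth_day = -12000L),
    observation_periods = data.frame(person_id = 1:n, start_day = -365L, end_day = 270L),
    exposures = data.frame(person_id = 1:n, vaccine_id = "vax", exposure_day = 30L),
    outcomes = data.frame(person_id = 1:4, outcome_id = "oc", outcome_day = 40L),
    config = scenario_config(n_persons = n, n_months = 9L)
  )
  r <- observed_rates(tabs, "vax", "oc", accrual_month = 9L)
  expect_equal(r$events, 4L)
  expect_equal(r$person_time, n * 28 / 365.25)
  expect_equal(r$rate, 4 / (n * 28 / 365.25))

  # accrual month before the first vaccination -> nothing estimable
  r0 <- observed_rates(tabs, "vax", "oc", accrual_month = 1L)
  expect_false(r0$estimable)
  expect_equal(r0$person_time, 0)
})

test_that("accrual equals filter-then-compute on truncated tables", {
  tabs <- sim_unbiased()
  cfg <- attr(tabs, "config")
  m <- 3L
  boundary <- cfg$surveillance_window[1] + m * 30L
  got <- observed_rates(tabs, "vax", "nc100", variant = design_variant(TRUE),
                        accrual_month = m)
  trunc <- tabs
  trunc$exposures <- tabs$exposures[exposure_day < boundary]
  trunc$outcomes <- tabs$outcomes[outcome_day < boundary]
  oracle <- observed_rates(trunc, "vax", "nc100", variant = design_variant(TRUE),
                           accrual_month = m)
  expect_equal(as.data.frame(got), as.data.frame(oracle))
})

test_that("stratum person-time adds up to the marginal person-time", {
  tabs <- sim_unbiased()
  adj <- historical_rates(tabs, "nc050", variant = design_variant(TRUE))
  marg <- historical_rates(tabs, "nc050", variant = design_variant(FALSE))
  expect_equal(sum(adj$person_time), marg$person_time)
  expect_equal(sum(adj$events), marg$events)
  oadj <- observed_rates(tabs, "vax", "nc050", variant = design_variant(TRUE))
  omarg <- observed_rates(tabs, "vax", "nc050", variant = design_variant(FALSE))
  expect_equal(sum(oadj$person_time), omarg$person_time)
})

test_that("expected count: six-stratum fixture and degenerate cases", {
  fx <- load_fixture("six_stratum_expected")
  ec <- expected_count(fx$background, fx$observed)
  expect_true(ec$estimable)
  expect_equal(ec$expected, fx$expected$expected_count)
  expect_equal(ec$n_hist, fx$expected$n_hist)

  # two-stratum arithmetic: {M: 0.1, F: 0.3}/py over 10 py each -> 4.0
  bg <- data.table::data.table(outcome_id = "x", age_band = NA_character_,
                               sex = c("M", "F"), events = c(1L, 3L),
                               person_time = 10, rate = c(0.1, 0.3),
                               estimable = TRUE)
  ob <- data.table::data.table(outcome_id = "x", age_band = NA_character_,
                               sex = c("M", "F"), events = 0L,
                               person_time = 10, rate = 0, estimable = TRUE)
  expect_equal(expected_count(bg, ob)$expected, 4.0)

  # all background rates zero -> E = 0 (downstream flags non-estimable)
  bg0 <- data.table::copy(bg)[, `:=`(rate = 0, events = 0L)]
  expect_equal(expected_count(bg0, ob)$expected, 0)

  # missing stratum with observed person-time -> non-estimable
  expect_false(expected_count(bg[sex == "M"], ob)$estimable)
})

test_that("anchoring raises background rates under visit-capture bias", {
  tabs <- sim_visit_capture()
  pooled <- function(variant) {
    r <- data.table::rbindlist(lapply(neg_ids(100)[seq(1, 100, by = 10)],
                                      function(id) historical_rates(tabs, id, variant = variant)))
    sum(r$events) / sum(r$person_time)
  }
  expect_gt(pooled(design_variant(anchored = TRUE)),
            1.5 * pooled(design_variant(anchored = FALSE)))
})
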