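# Generators: demographics, visits, uptake, outcomes, determinism and
# containment invariants.

test_that("population matches configured demographics", {
  cfg <- scenario_config(n_persons = 100000L, female_fraction = 0.511, seed = 9L)
  tabs <- generate_population(cfg)
  expect_equal(nrow(tabs$persons), 100000L)
  expect_equal(mean(tabs$persons$sex == "F"), 0.511, tolerance = 0.005 / 0.511)
  # one observation period per person, covering both windows
  expect_equal(nrow(tabs$observation_periods), 100000L)
  expect_true(all(tabs$observation_periods$start_day == cfg$historical_window[1]))
  expect_true(all(tabs$observation_periods$end_day == cfg$surveillance_window[2]))
})

test_that("empty population is a valid empty table set", {
  cfg <- scenario_config(n_persons = 0L)
  tabs <- simulate_scenario(cfg)
  for (nm in c("persons", "observation_periods", "visits", "exposures", "outcomes"))
    expect_equal(nrow(tabs[[nm]]), 0L)
  expect_silent(validate_event_tables(tabs))
})

test_that("invalid configurations are rejected", {
  expect_error(scenario_config(n_persons = -5), "n_persons")
  expect_error(scenario_config(10, female_fraction = 1.2), "female_fraction")
  expect_error(outcome_def("x", -1), "base_rate")
  expect_error(uptake_curve("rapid", coverage = 1.5), "coverage")
  expect_error(bias_knobs(healthy_vaccinee_shift = 0), "factors")
})

test_that("identical config and seed reproduce identical tables; different seeds differ", {
  cfg <- scenario_config(n_persons = 500L, outcome_defs = make_negatives(3),
                         seed = 77L)
  a <- simulate_scenario(cfg)
  b <- simulate_scenario(cfg)
  for (nm in c("persons", "observation_periods", "visits", "exposures", "outcomes"))
    expect_identical(as.data.frame(a[[nm]]), as.data.frame(b[[nm]]))
  cfg2 <- scenario_config(n_persons = 500L, outcome_defs = make_negatives(3),
                          seed = 78L)
  c_ <- simulate_scenario(cfg2)
  expect_false(identical(a$persons$birth_day, c_$persons$birth_day))
})

test_that("visit process hits its expected intensity and containment", {
  cfg <- scenario_config(n_persons = 1000L, visit_rate = 3, seed = 5L)
  tabs <- generate_visits(generate_population(cfg), cfg)
  op <- tabs$observation_periods
  expected <- 3 * sum(op$end_day - op$start_day) / 365.25
  expect_lt(abs(nrow(tabs$visits) - expected), 3 * sqrt(expected))
  expect_silent(validate_event_tables(tabs))

  cfg0 <- scenario_config(n_persons = 1000L, visit_rate = 0, seed = 5L)
  tabs0 <- generate_visits(generate_population(cfg0), cfg0)
  expect_equal(nrow(tabs0$visits), 0L)
})

test_that("rapid uptake concentrates doses early, slow spreads them", {
  cfg <- scenario_config(n_persons = 10000L,
                         uptake = uptake_curve("rapid", 0.4), seed = 11L)
  tabs <- generate_uptake(generate_visits(generate_population(cfg), cfg), cfg)
  expect_equal(nrow(tabs$exposures), 4000L)
  month <- tabs$exposures$exposure_day %/% 30L + 1L
  expect_gte(mean(month <= 2), 0.80)

  cfg_s <- scenario_config(n_persons = 10000L, n_months = 12L,
                           uptake = uptake_curve("slow", 0.4), seed = 11L)
  tabs_s <- generate_uptake(generate_visits(generate_population(cfg_s), cfg_s), cfg_s)
  month_s <- tabs_s$exposures$exposure_day %/% 30L + 1L
  expect_lt(mean(month_s <= 2), 0.30)  # ~2/12 expected
  expect_setequal(sort(unique(month_s)), 1:12)

  cfg0 <- scenario_config(n_persons = 1000L, uptake = uptake_curve("rapid", 0))
  tabs0 <- generate_uptake(generate_population(cfg0), cfg0)
  expect_equal(nrow(tabs0$exposures), 0L)
})

test_that("age confounding makes vaccinees older", {
  tabs <- sim_age_confounded()
  pers <- tabs$persons
  exposed <- pers$person_id %in% tabs$exposures$person_id
  age <- -pers$birth_day / 365.25
  d <- mean(age[exposed]) - mean(age[!exposed])
  se <- sqrt(var(age[exposed]) / sum(exposed) + var(age[!exposed]) / sum(!exposed))
  expect_gt(d, 3 * se)
})

test_that("outcome process hits its Poisson expectation", {
  cfg <- scenario_config(n_persons = 20000L,
                         outcome_defs = list(outcome_def("oc", 0.01)),
                         uptake = uptake_curve("rapid", 0), seed = 13L)
  tabs <- simulate_scenario(cfg)
  op <- tabs$observation_periods
  py <- sum(op$end_day - op$start_day) / 365.25
  expected <- 0.01 * py
  expect_lt(abs(nrow(tabs$outcomes) - expected), 3 * sqrt(expected))
  expect_silent(validate_event_tables(tabs))

  cfg0 <- scenario_config(n_persons = 1000L,
                          outcome_defs = list(outcome_def("oc", 0)))
  expect_equal(nrow(simulate_scenario(cfg0)$outcomes), 0L)
})

test_that("visit-capture boost doubles the recording rate after visits", {
  # oracle: classify person-days into boosted ([visit, visit+d]) and
  # unboosted time by merging visit windows per person, then compare
  # empirical rates between the two strata
  cfg <- scenario_config(n_persons = 2000L, visit_rate = 3,
                         outcome_defs = list(outcome_def("oc", 0.3)),
                         uptake = uptake_curve("rapid", 0),
                         bias = bias_knobs(visit_capture_boost = 2,
                                           visit_capture_days = 30L),
                         seed = 17L)
  tabs <- simulate_scenario(cfg)
  d <- 30L
  vis <- tabs$visits[order(person_id, visit_day)]
  op <- tabs$observation_periods
  all_days <- sum(op$end_day - op$start_day)  # same period for every person
  ev <- merge(tabs$outcomes, vis, by = "person_id", allow.cartesian = TRUE)
  ev[, in_win := outcome_day >= visit_day & outcome_day <= visit_day + d]
  ev_boost <- ev[, .(boosted = any(in_win)), by = .(person_id, outcome_day)]
  n_boost_events <- sum(ev_boost$boosted)
  n_plain_events <- nrow(tabs$outcomes) - n_boost_events
  # boosted person-days, exactly: count days within d after any visit
  pd <- vis[, {
    days <- unique(unlist(mapply(function(v) v:(v + d), visit_day,
                                 SIMPLIFY = FALSE)))
    .(nb = sum(days >= op$start_day[1] & days < op$end_day[1]))
  }, by = person_id]
  boosted_pd <- sum(pd$nb)
  plain_pd <- all_days - boosted_pd
  ratio <- (n_boost_events / boosted_pd) / (n_plain_events / plain_pd)
  se_log <- sqrt(1 / n_boost_events + 1 / n_plain_events)
  expect_lt(abs(log(ratio) - log(2)), 3 * se_log)
})

test_that("unbiased scenario: historical and surveillance rates agree", {
  tabs <- sim_unbiased()
  cfg <- attr(tabs, "config")
  hw <- cfg$historical_window
  sw <- cfg$surveillance_window
  ev <- tabs$outcomes
  n_hist <- nrow(ev[outcome_day >= hw[1] & outcome_day < hw[2]])
  n_surv <- nrow(ev[outcome_day >= sw[1] & outcome_day < sw[2]])
  # equal interval lengths and full observation -> equal expected counts
  se_log <- sqrt(1 / n_hist + 1 / n_surv)
  expect_lt(abs(log(n_surv / n_hist)), 3 * se_log)
})
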