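# Shared scenario builders and a lazy cache so expensive simulations are
# generated once per test run.

.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .sim_cache, inherits = FALSE))
    assign(key, builder(), envir = .sim_cache)
  get(key, envir = .sim_cache, inherits = FALSE)
}

neg_ids <- function(n, prefix = "nc") sprintf("%s%03d", prefix, seq_len(n))

# Background rates span the adverse-event-of-special-interest range; at
# these rates first-event depletion over the 270-day historical window is
# negligible, so the generator-unbiased scenario is also estimator-unbiased.
make_negatives <- function(n, rate_lo = 0.03, rate_hi = 0.1, ...) {
  rates <- seq(rate_lo, rate_hi, length.out = n)
  lapply(seq_len(n), function(i) outcome_def(neg_ids(n)[i], rates[i], ...))
}

# Unbiased mid-size scenario: 10,000 persons, 200 negative controls with
# background rates 0.03-0.1 per person-year, rapid uptake at 60% coverage.
unbiased_scenario <- function(n_outcomes = 200L, n_persons = 10000L, seed = 101L,
                              coverage = 0.6) {
  scenario_config(n_persons = n_persons, n_months = 9L,
                  uptake = uptake_curve("rapid", coverage),
                  outcome_defs = make_negatives(n_outcomes), seed = seed)
}

sim_unbiased <- function() cached("sim_unbiased", function() {
  simulate_scenario(unbiased_scenario())
})

est_unbiased <- function() cached("est_unbiased", function() {
  tabs <- sim_unbiased()
  controls <- control_definition(neg_ids(200))
  estimate_controls(tabs, controls, "vax",
                    designs = design_grid()["unadjusted"], months = 9L)
})

# Constant-bias scenario: healthy-vaccinee factor 2 multiplies every
# outcome's rate among vaccinees, giving the same log-scale shift for all
# controls (the calibration target).
sim_biased <- function() cached("sim_biased", function() {
  cfg <- scenario_config(n_persons = 10000L, n_months = 9L,
                         uptake = uptake_curve("rapid", 0.5),
                         outcome_defs = make_negatives(200L),
                         bias = bias_knobs(healthy_vaccinee_shift = 2),
                         seed = 202L)
  simulate_scenario(cfg)
})

est_biased_cal <- function() cached("est_biased_cal", function() {
  tabs <- sim_biased()
  syn <- synthesize_positive_controls(tabs, "vax", neg_ids(200), seed = 203L)
  est <- estimate_controls(syn$tables, syn$controls, "vax",
                           designs = design_grid()["unadjusted"], months = 9L)
  leave_one_out_calibrate(est)
})

# Age-confounded scenario: outcome rates rise ~7x from the youngest to the
# oldest band (a realistic adverse-event gradient) and vaccination
# propensity rises steeply with age; age-sex adjustment removes the
# confounding.
sim_age_confounded <- function() cached("sim_age_confounded", function() {
  defs <- lapply(seq_len(100), function(i)
    outcome_def(neg_ids(100)[i], 0.01 + 0.0003 * i,
                age_multipliers = 1.25^(0:9)))
  cfg <- scenario_config(n_persons = 10000L, n_months = 9L,
                         uptake = uptake_curve("rapid", 0.4),
                         outcome_defs = defs,
                         bias = bias_knobs(age_confounding_strength = 0.8),
                         seed = 303L)
  simulate_scenario(cfg)
})

# Visit-proximity recording scenario: outcomes are 3x as likely to be
# recorded within 30 days after a healthcare visit (vaccination visits
# included), inflating unanchored observed/expected ratios.
sim_visit_capture <- function() cached("sim_visit_capture", function() {
  cfg <- scenario_config(n_persons = 10000L, n_months = 9L,
                         uptake = uptake_curve("rapid", 0.4),
                         outcome_defs = make_negatives(100L, 0.05, 0.15),
                         bias = bias_knobs(visit_capture_boost = 3,
                                           visit_capture_days = 30L),
                         seed = 404L)
  simulate_scenario(cfg)
})
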