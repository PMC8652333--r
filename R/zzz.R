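#' @import data.table
#' @keywords internal
"_PACKAGE"

.datatable.aware <- TRUE

utils::globalVariables(c(
  ".", "N", "age_band", "bg_ok", "bg_rate", "cal_ci_high", "cal_ci_low",
  "cal_log_irr", "cal_mu", "cal_p", "cal_se", "cal_sigma", "ci_high",
  "ci_low", "control_id", "design", "detected", "estimable", "event",
  "exposure_day", "first_detection_month", "has_event", "index_day",
  "log_irr", "month", "outcome_day", "outcome_id", "p", "parent_id",
  "person_id", "person_time", "r", "rate", "ratio", "scenario_id",
  "se_log_irr", "sex", "true_irr", "type2_by_irr", "use_hi", "use_lo",
  "use_log_irr", "use_p", "use_se", "usable", "vaccine_id", "visit_day",
  "w_end", "w_start"
))
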