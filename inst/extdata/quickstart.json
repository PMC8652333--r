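{
  "scenario_id": "quickstart",
  "n_persons": 2000,
  "n_months": 9,
  "uptake": { "type": "rapid", "coverage": 0.5, "peak_month": 1 },
  "female_fraction": 0.511,
  "visit_rate": 3,
  "vaccine_id": "vax",
  "seed": 42,
  "bias": { "age_confounding_strength": 0, "healthy_vaccinee_shift": 1,
            "visit_capture_boost": 1, "visit_capture_days": 30 },
  "synthesis": { "irrs": [1.5, 2, 4], "min_outcomes": 25 },
  "outcomes": [
    { "outcome_id": "nc01", "base_rate": 0.05 },
    { "outcome_id": "nc02", "base_rate": 0.06 },
    { "outcome_id": "nc03", "base_rate": 0.07 },
    { "outcome_id": "nc04", "base_rate": 0.08 },
    { "outcome_id": "nc05", "base_rate": 0.09 },
    { "outcome_id": "nc06", "base_rate": 0.10 },
    { "outcome_id": "nc07", "base_rate": 0.11, "sex_multiplier": 1.4 },
    { "outcome_id": "nc08", "base_rate": 0.12 },
    { "outcome_id": "nc09", "base_rate": 0.13 },
    { "outcome_id": "nc10", "base_rate": 0.14 },
    { "outcome_id": "nc11", "base_rate": 0.15 },
    { "outcome_id": "nc12", "base_rate": 0.16 }
  ]
}
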