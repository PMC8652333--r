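# Reading and writing the event tables and scenario configs. Stage outputs
# are plain delimited files plus a JSON sidecar echoing the full scenario
# configuration, so any stage can be rerun or audited independently.

scenario_to_list <- function(config) {
  list(
    n_persons = config$n_persons, n_months = config$n_months,
    uptake = unclass(config$uptake),
    female_fraction = config$female_fraction,
    age_weights = config$age_weights,
    visit_rate = config$visit_rate,
    outcomes = lapply(config$outcome_defs, unclass),
    bias = unclass(config$bias),
    vaccine_id = config$vaccine_id,
    seed = config$seed
  )
}

#' Build a scenario config from a plain list (parsed JSON/YAML)
#'
#' Accepts the schema written by [write_event_tables()] sidecars and CLI
#' config files; unknown fields are ignored, missing ones take the
#' [scenario_config()] defaults.
#'
#' @param x a named list.
#' @return a [scenario_config()].
#' @export
scenario_from_list <- function(x) {
  upt <- x$uptake %||% list()
  bia <- x$bias %||% list()
  oc_in <- x$outcomes %||% list()
  if (is.data.frame(oc_in))
    oc_in <- lapply(seq_len(nrow(oc_in)), function(i) as.list(oc_in[i, ]))
  # fields absent from a JSON record may arrive as NULL or (via data.frame
  # simplification) as NA; both mean "use the default"
  or_default <- function(v, d) {
    v <- unlist(v)
    if (is.null(v) || all(is.na(v))) d else v
  }
  ocs <- lapply(oc_in, function(o)
    outcome_def(o$outcome_id, o$base_rate,
                or_default(o$age_multipliers, rep(1, 10)),
                or_default(o$sex_multiplier, 1),
                or_default(o$seasonal_amplitude, 0),
                or_default(o$secular_slope, 0)))
  scenario_config(
    n_persons = x$n_persons,
    n_months = x$n_months %||% 9L,
    uptake = uptake_curve(upt$type %||% "rapid", upt$coverage %||% 0.5,
                          upt$peak_month %||% 1L),
    female_fraction = x$female_fraction %||% 0.511,
    age_weights = x$age_weights %||% .default_age_weights,
    visit_rate = x$visit_rate %||% 3,
    outcome_defs = ocs,
    bias = bias_knobs(bia$age_confounding_strength %||% 0,
                      bia$healthy_vaccinee_shift %||% 1,
                      bia$visit_capture_boost %||% 1,
                      bia$visit_capture_days %||% 30L),
    vaccine_id = x$vaccine_id %||% "vax",
    seed = x$seed %||% 1L
  )
}

#' Read a scenario config file (JSON, or YAML when the yaml package is
#' available)
#'
#' @param path file path.
#' @return a [scenario_config()] plus a `scenario_id` attribute if the file
#'   declares one, and a `synthesis` attribute (`irrs`, `min_outcomes`) when
#'   present.
#' @export
read_scenario_config <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop_config("YAML config given but the yaml package is not installed")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  cfg <- scenario_from_list(x)
  attr(cfg, "scenario_id") <- x$scenario_id %||% "scenario"
  attr(cfg, "synthesis") <- x$synthesis
  cfg
}

#' Write event tables to a directory
#'
#' One CSV per table plus `scenario.json` echoing the full configuration and
#' seed.
#'
#' @param tables an `event_tables`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_event_tables <- function(tables, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in c("persons", "observation_periods", "visits", "exposures", "outcomes"))
    data.table::fwrite(tables[[nm]], file.path(dir, paste0(nm, ".csv")))
  config <- attr(tables, "config")
  if (!is.null(config))
    jsonlite::write_json(scenario_to_list(config),
                         file.path(dir, "scenario.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read event tables back from a directory
#'
#' @param dir directory written by [write_event_tables()].
#' @return an `event_tables` (with its config reattached when the sidecar is
#'   present).
#' @export
read_event_tables <- function(dir) {
  config <- NULL
  sidecar <- file.path(dir, "scenario.json")
  if (file.exists(sidecar))
    config <- scenario_from_list(jsonlite::read_json(sidecar, simplifyVector = TRUE))
  tabs <- empty_event_tables(config)
  for (nm in names(tabs)) {
    f <- file.path(dir, paste0(nm, ".csv"))
    if (file.exists(f)) {
      dt <- data.table::fread(f, colClasses = vapply(tabs[[nm]], class, ""))
      if (nrow(dt)) tabs[[nm]] <- dt
    }
  }
  structure(tabs, class = "event_tables", config = config)
}
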