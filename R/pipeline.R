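# End-to-end orchestration: scenario -> tables -> control synthesis ->
# estimates (4 designs x accrual months) -> leave-one-out calibration ->
# estimability filtering -> metrics and timeliness -> report, with a run
# manifest for provenance. Every stage output is a file so stages can be
# rerun or inspected independently.

#' Run a full benchmark experiment
#'
#' @param config a [scenario_config()], or the path of a JSON/YAML config
#'   file (see [read_scenario_config()]). Every outcome in the scenario is
#'   treated as a negative control.
#' @param out output directory.
#' @param months accrual months to evaluate; default `1:n_months`.
#' @param designs design variants; default all four.
#' @param irrs positive-control target IRRs.
#' @param min_outcomes synthesis threshold on parent exposed time-at-risk
#'   events.
#' @param window post-vaccination [tar_window()].
#' @param write_tables also persist the raw event tables?
#' @return invisibly, a list with `tables`, `controls`, `estimates`
#'   (calibration columns included), `metrics` (uncalibrated and calibrated
#'   rows bound together), `timeliness`, `exclusions`, `manifest`.
#' @export
run_experiment <- function(config, out, months = NULL, designs = design_grid(),
                           irrs = c(1.5, 2, 4), min_outcomes = 25L,
                           window = tar_window(), write_tables = TRUE) {
  scenario_id <- "scenario"
  if (is.character(config)) {
    path <- config
    config <- read_scenario_config(path)
    scenario_id <- attr(config, "scenario_id") %||% "scenario"
    syn_cfg <- attr(config, "synthesis")
    if (!is.null(syn_cfg)) {
      irrs <- unlist(syn_cfg$irrs) %||% irrs
      min_outcomes <- syn_cfg$min_outcomes %||% min_outcomes
    }
  }
  stopifnot(inherits(config, "scenario_config"))
  months <- as.integer(months %||% seq_len(config$n_months))
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  tables <- simulate_scenario(config)
  validate_event_tables(tables)
  if (write_tables) write_event_tables(tables, file.path(out, "tables"))

  negative_ids <- vapply(config$outcome_defs, function(d) as.character(d$outcome_id), "")
  syn <- synthesize_positive_controls(tables, config$vaccine_id, negative_ids,
                                      window, irrs, min_outcomes,
                                      seed = derive_seed(config$seed, 97L))
  data.table::fwrite(syn$manifest, file.path(out, "control_manifest.csv"))
  data.table::fwrite(syn$controls, file.path(out, "controls.csv"))

  estimates <- estimate_controls(syn$tables, syn$controls, config$vaccine_id,
                                 window, designs, months)
  estimates <- leave_one_out_calibrate(estimates)
  data.table::fwrite(estimates, file.path(out, "estimates.csv"))

  rates <- monthly_population_rates(syn$tables, negative_ids)
  data.table::fwrite(rates, file.path(out, "population_rates.csv"))
  filt <- estimability_filter(estimates, rates)
  data.table::fwrite(filt$exclusions, file.path(out, "exclusions.csv"))

  metrics <- rbind(metrics_table(filt$estimates, calibrated = FALSE),
                   metrics_table(filt$estimates, calibrated = TRUE))
  flat <- flatten_metrics(metrics)
  flat[, scenario_id := scenario_id]
  data.table::fwrite(flat, file.path(out, "metrics.csv"))

  timeliness <- timeliness_table(filt$estimates, calibrated = FALSE)
  data.table::fwrite(timeliness, file.path(out, "timeliness.csv"))

  manifest <- run_manifest(scenario_id, config, out)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(tables = syn$tables, controls = syn$controls,
                 estimates = estimates, metrics = metrics,
                 timeliness = timeliness, exclusions = filt$exclusions,
                 manifest = manifest))
}

# Expand the per-IRR type 2 list column into flat columns for file output.
flatten_metrics <- function(metrics) {
  m <- data.table::copy(metrics)
  irrs <- sort(unique(unlist(lapply(m$type2_by_irr, function(t)
    if (is.data.frame(t)) t$true_irr else NULL))))
  for (r in irrs) {
    col <- sprintf("type2_irr%g", r)
    m[, (col) := vapply(type2_by_irr, function(t) {
      if (!is.data.frame(t)) return(NA_real_)
      v <- t$type2[t$true_irr == r]
      if (length(v)) v else NA_real_
    }, 0)]
  }
  m[, type2_by_irr := NULL]
  m[]
}

# Provenance manifest: config hash, seed, package version, per-file digests.
run_manifest <- function(scenario_id, config, out) {
  files <- list.files(out, recursive = TRUE, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  digests <- as.list(tools::md5sum(files))
  names(digests) <- sub(paste0("^", out, "/?"), "", names(digests))
  cfg_json <- jsonlite::toJSON(scenario_to_list(config), auto_unbox = TRUE,
                               digits = NA)
  list(scenario_id = scenario_id,
       seed = config$seed,
       config_md5 = unname(tools::md5sum(textConnection2file(cfg_json))),
       package_version = as.character(utils::packageVersion("oebench")),
       files = digests,
       timestamp = format(Sys.time(), tz = "UTC"))
}

# md5sum needs a file; hash the config JSON via a temp file.
textConnection2file <- function(txt) {
  f <- tempfile(fileext = ".json")
  writeLines(txt, f)
  f
}

#' Summarise a metrics table as a plain-text report
#'
#' One summary block per scenario and design, listing type 1/2 error, AUC,
#' coverage and precision at the final evaluated month, before and after
#' calibration. Optional base-graphics plots of the type 1/2 trade-off and
#' monthly timeliness curves.
#'
#' @param metrics flat metrics table (as written by [run_experiment()]).
#' @param file output text file (default: print to console).
#' @param plots optional directory for PNG plots; `NULL` (default) for none.
#' @param timeliness optional timeliness table for the detection-month plot.
#' @return the report lines, invisibly.
#' @export
report <- function(metrics, file = "", plots = NULL, timeliness = NULL) {
  metrics <- data.table::as.data.table(metrics)
  if (nrow(metrics) == 0L) {
    warning("empty metrics table; writing empty report")
    if (nzchar(file)) writeLines(character(), file)
    return(invisible(character()))
  }
  last <- metrics[, .SD[month == max(month)], by = .(design, calibrated)]
  lines <- c("observed-vs-expected benchmark report", "")
  for (sid in unique(metrics$scenario_id %||% "scenario")) {
    lines <- c(lines, sprintf("scenario: %s", sid))
    for (i in seq_len(nrow(last))) {
      r <- last[i]
      lines <- c(lines, sprintf(
        "  %-18s %-12s month %2d | type1 %.2f type2 %s auc %s coverage %s precision %s",
        r$design, ifelse(r$calibrated, "calibrated", "uncalibrated"), r$month,
        r$type1, fmt_or_na(r$type2), fmt_or_na(r$auc), fmt_or_na(r$coverage),
        fmt_or_na(r$mean_precision)))
    }
  }
  if (nzchar(file)) writeLines(lines, file) else writeLines(lines)
  if (!is.null(plots)) {
    dir.create(plots, recursive = TRUE, showWarnings = FALSE)
    grDevices::png(file.path(plots, "type1_type2.png"), width = 700, height = 500)
    graphics::par(mfrow = c(1, 2))
    for (cal in unique(last$calibrated)) {
      sub <- last[calibrated == cal]
      graphics::barplot(rbind(sub$type1, sub$type2), beside = TRUE,
                        names.arg = sub$design, las = 2,
                        legend.text = c("type 1", "type 2"), ylim = c(0, 1),
                        main = ifelse(cal, "calibrated", "uncalibrated"))
    }
    grDevices::dev.off()
    if (!is.null(timeliness)) {
      grDevices::png(file.path(plots, "timeliness.png"), width = 700, height = 500)
      tl <- data.table::as.data.table(timeliness)
      graphics::boxplot(first_detection_month ~ true_irr, data = tl,
                        xlab = "true IRR", ylab = "first detection month")
      grDevices::dev.off()
    }
  }
  invisible(lines)
}

fmt_or_na <- function(x) ifelse(is.na(x), "NA", sprintf("%.2f", x))

#' Command-line entry point
#'
#' Verbs: `run` (full pipeline) and `report`. Typical use from
#' `inst/cli/oebench.R`:
#' `Rscript oebench.R run --config scenario.json --out DIR [--seed N]`.
#'
#' @param args character vector of CLI arguments (default
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return exit status 0 on success, invisibly.
#' @export
oebench_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: oebench <run|simulate|report> --config FILE --out DIR [--seed N]"
  if (length(args) < 1L) stop(usage, call. = FALSE)
  verb <- args[1]
  opt <- list()
  i <- 2L
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    opt[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  if (is.null(opt$out)) stop(usage, call. = FALSE)
  if (verb %in% c("run", "simulate")) {
    if (is.null(opt$config)) stop(usage, call. = FALSE)
    config <- read_scenario_config(opt$config)
    if (!is.null(opt$seed)) config$seed <- as.integer(opt$seed)
    if (verb == "simulate") {
      write_event_tables(simulate_scenario(config), opt$out)
    } else {
      run_experiment(config, opt$out)
    }
  } else if (verb == "report") {
    metrics <- data.table::fread(file.path(opt$out, "metrics.csv"))
    tl_file <- file.path(opt$out, "timeliness.csv")
    tl <- if (file.exists(tl_file)) data.table::fread(tl_file) else NULL
    report(metrics, file.path(opt$out, "report.txt"),
           plots = if (!is.null(opt$plots) && opt$plots == "true")
             file.path(opt$out, "plots") else NULL,
           timeliness = tl)
  } else {
    stop(usage, call. = FALSE)
  }
  invisible(0L)
}
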