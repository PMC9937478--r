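# io_cli module: bundle readers/writers (CSV + YAML), run configuration,
# result persistence, and the reported-component worked-example tables

#' Write an input bundle to a directory
#'
#' Persists the four input tables as UTF-8 comma-separated files with header
#' rows and period decimal separators (`strata.csv`, `rr_table.csv`,
#' `cost_table.csv`, `mortality.csv`) plus a `config.yaml` holding the scalar
#' parameters (scenario intakes, bins, dose-response, labor, currency, and
#' optionally Monte Carlo settings). Currency is stored in raw units, never
#' thousands; scaling to "thousand USD" happens only when rendering reports.
#'
#' @param bundle a `salt_bundle`.
#' @param dir output directory (created if needed).
#' @param mc optional [mc_config()] to embed in the config file.
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir, mc = NULL) {
  validate_bundle(bundle)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    write.csv(df, file.path(dir, name), row.names = FALSE, quote = FALSE)
  }
  wr(bundle$strata, "strata.csv")
  wr(bundle$rr_table, "rr_table.csv")
  wr(bundle$cost_table, "cost_table.csv")
  wr(bundle$mortality, "mortality.csv")
  cfg <- list(
    scenario = list(
      baseline = list(mean = bundle$baseline$mean, sd = bundle$baseline$sd,
                      kcal = bundle$baseline$kcal),
      counterfactual = list(mean = bundle$counterfactual$mean,
                            sd = bundle$counterfactual$sd,
                            kcal = bundle$counterfactual$kcal)
    ),
    bins = list(start = bundle$bins$lower[2],
                stop = bundle$bins$lower[length(bundle$bins$lower)],
                width = bundle$bins$width,
                reference = bundle$bins$reference),
    dose_response = unclass(bundle$dose_response),
    labor = unclass(bundle$labor),
    currency = unclass(bundle$currency),
    tables = list(strata = "strata.csv", rr = "rr_table.csv",
                  costs = "cost_table.csv", mortality = "mortality.csv")
  )
  if (!is.null(mc)) cfg$mc <- unclass(mc)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}

read_table_file <- function(path, field) {
  if (!file.exists(path)) abort_invalid("file not found", field)
  as_tibble(read.csv(path, stringsAsFactors = FALSE))
}

#' Load a run configuration
#'
#' Parses a YAML (or JSON) configuration, reads the referenced input tables
#' (paths resolved relative to the configuration file), and validates every
#' invariant; violations are reported with the offending field path (e.g.
#' `labor.participation_rate`). Distinct errors are raised for a missing
#' file, an unparsable file, and an invariant violation.
#'
#' @param path path to the configuration file.
#' @return a `run_config` list with elements `bundle` (a validated
#'   `salt_bundle`), `mc` (an [mc_config()] or `NULL`), and `output_dir`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort_invalid("file not found", path)
  cfg <- tryCatch(
    yaml::read_yaml(path),
    error = function(e) {
      abort_invalid(sprintf("cannot parse: %s", conditionMessage(e)), path)
    })
  for (f in c("scenario", "bins", "dose_response", "labor", "currency",
              "tables")) {
    if (is.null(cfg[[f]])) abort_invalid("missing section", f)
  }
  base_dir <- dirname(normalizePath(path))
  tbl <- function(key) {
    p <- cfg$tables[[key]]
    if (is.null(p)) abort_invalid("missing table path", paste0("tables.", key))
    read_table_file(if (file.exists(p)) p else file.path(base_dir, p),
                    paste0("tables.", key))
  }
  mk <- function(ctor, args, keep) do.call(ctor, args[intersect(names(args), keep)])
  bundle <- new_bundle(
    strata = tbl("strata"),
    baseline = mk(intake_distribution, cfg$scenario$baseline,
                  c("mean", "sd", "kcal")),
    counterfactual = mk(intake_distribution, cfg$scenario$counterfactual,
                        c("mean", "sd", "kcal")),
    rr_table = tbl("rr"),
    cost_table = tbl("costs"),
    mortality = tbl("mortality"),
    labor = mk(labor_params, cfg$labor,
               names(formals(labor_params))),
    currency = mk(currency_rate, cfg$currency, "crc_per_usd"),
    dose_response = mk(dose_response_spec, cfg$dose_response,
                       c("sbp_drop_mmHg", "per_salt_drop_g")),
    bins = mk(bin_scheme, cfg$bins, c("start", "stop", "width", "reference"))
  )
  bundle$cost_table$available <- as.logical(bundle$cost_table$available)
  validate_bundle(bundle)
  mc <- if (!is.null(cfg$mc)) mk(mc_config, cfg$mc, names(formals(mc_config)))
  structure(list(bundle = bundle, mc = mc,
                 output_dir = cfg$output_dir %||% NULL),
            class = "run_config")
}

#' Read an input bundle written by [write_bundle()]
#'
#' @param dir directory containing `config.yaml` and the table CSVs.
#' @return a validated `salt_bundle`.
#' @export
read_bundle <- function(dir) {
  load_config(file.path(dir, "config.yaml"))$bundle
}

#' Save pipeline results to a directory
#'
#' Writes every result table as CSV, the headline outputs as JSON, and a run
#' log (`run_log.json`) carrying the input-bundle hash, seed, draw count and
#' package version — enough to reproduce any result file. Outputs contain no
#' timestamps, so two runs with the same inputs and seed produce
#' byte-identical files.
#'
#' @param result a `salt_result` from [run_pipeline()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_results <- function(result, dir) {
  stopifnot(inherits(result, "salt_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    write.csv(df, file.path(dir, name), row.names = FALSE, quote = FALSE)
  }
  wr(result$paf, "stratum_paf.csv")
  wr(result$pooled_par, "pooled_par.csv")
  wr(result$direct_cells, "direct_cells.csv")
  wr(result$direct_report$by_service, "direct_by_service.csv")
  wr(result$direct_report$by_disease, "direct_by_disease.csv")
  wr(result$direct_report$by_sex, "direct_by_sex.csv")
  wr(result$productivity, "productivity.csv")
  if (!is.null(result$mc)) wr(result$mc, "mc_summary.csv")
  jsonlite::write_json(as.list(result$outputs), file.path(dir, "outputs.json"),
                       auto_unbox = TRUE, digits = NA)
  log <- list(
    bundle_hash = rlang::hash(result$bundle),
    counterfactual_mode = result$counterfactual_mode,
    seed = if (!is.null(result$mc_config)) result$mc_config$seed,
    mc_draws = if (!is.null(result$mc)) result$mc$n_draws[1],
    package_version = as.character(utils::packageVersion("saltcost")),
    r_version = paste(R.version$major, R.version$minor, sep = ".")
  )
  jsonlite::write_json(log[!vapply(log, is.null, logical(1))],
                       file.path(dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Reported attributable-cost components for Costa Rica 2018
#'
#' Component cells of the published attributable-cost and productivity-loss
#' tables for Costa Rica 2018, in thousand USD. These are the worked-example
#' inputs for the aggregation layer: feeding each table's own component cells
#' through [cost_report()] / [productivity_report()] reproduces its printed
#' totals and integer-percent shares. Medication cells for stroke and
#' rheumatic heart disease are absent (the payer could not cost them), not
#' zero.
#'
#' @param table which component set: `"services"` (the three service totals
#'   across all cardiovascular disease), `"by_disease"` (disease x service
#'   body cells), `"hospitalization"`, `"consultation"`, `"medication"`
#'   (disease x sex), or `"productivity"` (outcome x sex).
#' @return tibble with key columns and `value` (thousand USD).
#' @export
#' @examples
#' cost_report(reported_components("services"))$grand_total  # 15122
reported_components <- function(table = c("services", "by_disease",
                                          "hospitalization", "consultation",
                                          "medication", "productivity")) {
  table <- match.arg(table)
  path <- system.file("extdata", "cr2018_reported_components.csv",
                      package = "saltcost", mustWork = TRUE)
  all <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
  out <- all[all$table == table, setdiff(names(all), "table")]
  out <- out[, colSums(!is.na(out)) > 0]
  rename(out, value = "value_thousand_usd")
}
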