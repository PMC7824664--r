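# Reporting layer: the cmd_* functions tie the modules together behind the
# command-line interface (inst/cli/rnavaxcap.R). Reports are deterministic:
# the same inputs always produce byte-identical CSV/JSON artifacts, and every
# reported number is reproducible from the echoed inputs.

resolve_config <- function(config) {
  if (is.null(config)) {
    list(cfg = list(vaccine = NULL, process = process_params(),
                    cost = cost_params(), demand = demand_spec()),
         source = "default", path = NA_character_)
  } else if (inherits(config, "vaxcap_config")) {
    list(cfg = config, source = "config", path = NA_character_)
  } else if (is.character(config)) {
    list(cfg = load_config(config), source = "config", path = config)
  } else stop_field("config", "must be NULL, a path or a vaxcap_config")
}

resolve_scenarios <- function(cfg, scenarios) {
  if (!is.null(cfg$vaccine) && identical(scenarios, "config"))
    return(stats::setNames(list(cfg$vaccine), cfg$vaccine$name))
  presets <- vaccine_presets()
  if (identical(scenarios, "all") || identical(scenarios, "config")) {
    if (!is.null(cfg$vaccine))
      return(stats::setNames(list(cfg$vaccine), cfg$vaccine$name))
    return(presets)
  }
  missing <- setdiff(scenarios, names(presets))
  if (length(missing))
    stop_field("scenario", paste0("unknown scenario(s): ",
                                  paste(missing, collapse = ", ")))
  presets[scenarios]
}

new_run_report <- function(command, inputs, table) {
  structure(list(command = command, inputs = inputs, table = table,
                 tool_version = as.character(packageVersion("rnavaxcap"))),
            class = "run_report")
}

report_inputs <- function(res, demand, demand_source) {
  list(config = res$path, config_source = res$source,
       process = unclass(res$cfg$process), cost = unclass(res$cfg$cost),
       demand = unclass(demand), demand_source = demand_source)
}

#' Capacity and resource report
#'
#' Produces the resource-requirement table for the selected vaccines at
#' their feasible line scales under the low / medium / high titre scenarios:
#' total CapEx, annual OpEx, cost per dose, total production scale, required
#' batches and facility count for the annual dose demand.
#'
#' @param config `NULL` (all defaults), a path to a JSON config, or a
#'   `vaxcap_config`. A config carrying a `vaccine` section restricts the
#'   report to that vaccine.
#' @param demand Demand override, annual doses (numeric), or `NULL` to use
#'   the config/default demand.
#' @param scenarios `"all"`, or a character vector of built-in scenario
#'   names (ignored when the config defines its own vaccine).
#' @param out Optional output directory; when given, CSV or JSON artifacts
#'   are written there.
#' @param format `"csv"` or `"json"`.
#' @return A `run_report` whose `table` has one row per scenario and titre
#'   case.
#' @examples
#' rep <- cmd_capacity()
#' subset(rep$table, case == "medium", c(scenario, facilities))
#' @export
cmd_capacity <- function(config = NULL, demand = NULL, scenarios = "all",
                         out = NULL, format = c("csv", "json")) {
  format <- match.arg(format)
  res <- resolve_config(config)
  cfg <- res$cfg
  demand_source <- if (!is.null(demand)) "override"
  else if (res$source == "config") "config" else "default"
  dm <- if (is.null(demand)) cfg$demand else {
    check_number(demand, "demand", lower = 0)
    d <- unclass(cfg$demand)
    if (demand > 0) {
      d$annual_doses <- demand
      d$population <- max(d$population, demand)  # keep invariant
      do.call(demand_spec, d)
    } else NULL  # zero demand handled below without the >0 invariant
  }
  scen <- resolve_scenarios(cfg, scenarios)
  rows <- lapply(scen, function(sc) {
    if (is.null(dm)) {  # zero-demand degenerate case
      cases <- c("low", "medium", "high")
      pert <- c(0.8, 1, 1.2)
      return(data.frame(
        scenario = sc$name, case = cases, titre = cfg$process$titre * pert,
        volume = sc$feasible_scale, capex_total = 0, opex_annual = 0,
        cost_per_dose = NA_real_, total_scale_L = 0, batches = 0,
        facilities = 0))
    }
    ts <- titre_scenarios(sc, cfg$process, cfg$cost, dm)
    do.call(rbind, lapply(names(ts), function(case) {
      x <- ts[[case]]
      data.frame(
        scenario = sc$name, case = case, titre = x$titre,
        volume = x$capacity$volume,
        capex_total = x$cost$capex_total,
        opex_annual = x$cost$opex_annual,
        cost_per_dose = x$cost_per_dose,
        total_scale_L = x$capacity$required_total_volume,
        batches = x$capacity$required_batches_rounded,
        facilities = as.integer(x$capacity$facilities))
    }))
  })
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  rep <- new_run_report("capacity",
                        report_inputs(res, dm %||% list(annual_doses = 0),
                                      demand_source), table)
  if (!is.null(out)) write_report(rep, out, format)
  rep
}

#' Production timeline report
#'
#' Time for a single line to produce the annual dose demand, per vaccine, at
#' the vaccine's feasible scale and at the 30 L scale-up limit, under the
#' low / medium / high titre scenarios. Uses the nominal-recovery timeline
#' convention.
#'
#' @inheritParams cmd_capacity
#' @return A `run_report`; the table has columns `scenario`, `volume`,
#'   `case`, `titre`, `years`, `months`, `days`.
#' @examples
#' rep <- cmd_timeline()
#' subset(rep$table, scenario == "saRNA-1" & volume == 30 & case == "medium")
#' @export
cmd_timeline <- function(config = NULL, demand = NULL, scenarios = "all",
                         out = NULL, format = c("csv", "json")) {
  format <- match.arg(format)
  res <- resolve_config(config)
  cfg <- res$cfg
  demand_source <- if (!is.null(demand)) "override"
  else if (res$source == "config") "config" else "default"
  dm <- cfg$demand
  if (!is.null(demand)) {
    check_number(demand, "demand", lower = 0, strict_lower = TRUE)
    d <- unclass(dm); d$annual_doses <- demand
    d$population <- max(d$population, demand)
    dm <- do.call(demand_spec, d)
  }
  scen <- resolve_scenarios(cfg, scenarios)
  pert <- c(low = 0.8, medium = 1, high = 1.2)
  rows <- lapply(scen, function(sc) {
    vols <- unique(c(sc$feasible_scale, 30))
    do.call(rbind, lapply(vols, function(v) {
      do.call(rbind, lapply(names(pert), function(case) {
        titre <- cfg$process$titre * pert[[case]]
        yrs <- time_to_demand(dm$annual_doses, sc$rna_per_dose, v, titre,
                              cfg$process$nominal_recovery,
                              cfg$process$capacity_anchors)
        data.frame(scenario = sc$name, volume = v, case = case,
                   titre = titre, years = yrs, months = yrs * 12,
                   days = yrs * 365)
      }))
    }))
  })
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  rep <- new_run_report("timeline", report_inputs(res, dm, demand_source),
                        table)
  if (!is.null(out)) write_report(rep, out, format)
  rep
}

#' Tornado sensitivity report
#'
#' @inheritParams cmd_capacity
#' @return A `run_report` whose `table` is the [tornado()] table.
#' @export
cmd_tornado <- function(config = NULL, out = NULL,
                        format = c("csv", "json")) {
  format <- match.arg(format)
  res <- resolve_config(config)
  cfg <- res$cfg
  scenario <- cfg$vaccine %||% vaccine_presets()[["mRNA-30"]]
  bl <- tornado_baseline(scenario, cfg$process, cfg$cost)
  table <- tornado(bl)
  rep <- new_run_report("tornado",
                        report_inputs(res, cfg$demand, res$source), table)
  if (!is.null(out)) write_report(rep, out, format)
  rep
}

#' Fill-to-finish bottleneck report
#'
#' @inheritParams cmd_capacity
#' @param line A [fill_line()].
#' @return A `run_report` whose `table` is the [fillfinish_report()] table.
#' @export
cmd_fillfinish <- function(config = NULL, line = fill_line(), out = NULL,
                           format = c("csv", "json")) {
  format <- match.arg(format)
  res <- resolve_config(config)
  cfg <- res$cfg
  scen <- resolve_scenarios(cfg, "all")
  table <- fillfinish_report(scen, cfg$process, line)
  rep <- new_run_report("fillfinish",
                        report_inputs(res, cfg$demand, res$source), table)
  rep$inputs$fill_line <- unclass(line)
  if (!is.null(out)) write_report(rep, out, format)
  rep
}

#' Effective-recovery calibration report
#'
#' Reads a CSV table of published batch requirements (columns
#' `rna_per_dose`, `titre`, `volume`, `batches`) and refits the effective
#' recovery, see [recalibrate_recovery()].
#'
#' @param table_path Path to the CSV table; defaults to the shipped fixture
#'   of published values.
#' @param demand Annual dose demand behind the table.
#' @inheritParams cmd_capacity
#' @return A `run_report` with the fitted `recovery` in `inputs` and the
#'   per-row residual table in `table`.
#' @export
cmd_calibrate <- function(table_path = system.file(
                            "extdata", "printed_batch_requirements.csv",
                            package = "rnavaxcap"),
                          demand = 8e9, out = NULL,
                          format = c("csv", "json")) {
  format <- match.arg(format)
  if (!file.exists(table_path))
    stop(sprintf("table file not found: %s", table_path), call. = FALSE)
  tab <- read.csv(table_path)
  fit <- recalibrate_recovery(tab, demand_doses = demand)
  rep <- new_run_report("calibrate",
                        list(table = table_path, demand = demand,
                             recovery = fit$recovery,
                             residual_loss_factor = fit$recovery /
                               (0.56 * 0.95)),
                        fit$table)
  if (!is.null(out)) write_report(rep, out, format)
  rep
}

#' Write a run report to disk
#'
#' Writes `<command>.csv` (table only) or `<command>.json` (inputs echo,
#' table and tool version) into a directory. Output is deterministic:
#' repeated identical invocations produce byte-identical files.
#'
#' @param report A `run_report`.
#' @param out Output directory (created if missing).
#' @param format `"csv"` or `"json"`.
#' @return Path(s) of the file(s) written, invisibly.
#' @export
write_report <- function(report, out, format = c("csv", "json")) {
  format <- match.arg(format)
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  path <- file.path(out, paste0(report$command, ".", format))
  if (format == "csv") {
    write.csv(report$table, path, row.names = FALSE)
  } else {
    jsonlite::write_json(
      list(command = report$command, tool_version = report$tool_version,
           inputs = report$inputs, table = report$table),
      path, auto_unbox = TRUE, digits = NA, dataframe = "rows",
      pretty = TRUE)
  }
  invisible(path)
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %s (rnavaxcap %s)\n", x$command,
              x$tool_version))
  print(x$table)
  invisible(x)
}
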