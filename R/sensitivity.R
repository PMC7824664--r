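#' Default tornado parameter ranges
#'
#' The four process uncertainties use the studied ranges (RNA per dose
#' 0.1-100 ug, scale 1-50 L, titre 2-7 g/L, failure rate 0-15%); the cost
#' parameters, whose ranges are only shown graphically in the source
#' analysis, default to 0.5x-2x their baseline values.
#'
#' @param baseline A `tornado_baseline` list, see [tornado_baseline()].
#' @return Named list of `c(low, high)` ranges.
#' @export
default_tornado_ranges <- function(baseline = tornado_baseline()) {
  cs <- baseline$costs
  list(
    rna_per_dose = c(0.1, 100),
    volume = c(1, 50),
    titre = c(2, 7),
    failure_rate = c(0, 0.15),
    cleancap_price = cs$cleancap_price * c(0.5, 2),
    mod_utp_price = cs$mod_utp_price * c(0.5, 2),
    labour_rate = cs$labour_rate * c(0.5, 2),
    qc_fraction = cs$qc_fraction * c(0.5, 2)
  )
}

#' Baseline operating point for the tornado analysis
#'
#' A single 30 L line producing a 30 ug/dose modified-UTP vaccine at 5 g/L
#' titre and 5% failure rate, with all cost parameters at their defaults.
#'
#' @param scenario,process,costs Overrides for the three parameter sets.
#' @return A list of class `tornado_baseline`.
#' @export
tornado_baseline <- function(scenario = vaccine_presets()[["mRNA-30"]],
                             process = process_params(),
                             costs = cost_params()) {
  structure(list(scenario = scenario, process = process, costs = costs),
            class = "tornado_baseline")
}

# evaluate single-line annual doses and cost per dose with one parameter
# overridden
tornado_eval <- function(baseline, param, value) {
  sc <- baseline$scenario
  pr <- unclass(baseline$process)
  cs <- unclass(baseline$costs)
  dose <- sc$rna_per_dose
  if (param == "rna_per_dose") dose <- value
  else if (param %in% names(pr)) pr[[param]] <- value
  else if (param %in% names(cs)) cs[[param]] <- value
  else stop_field("parameter", paste0("unknown tornado parameter: ", param))
  pr <- do.call(process_params, pr)
  cs <- do.call(cost_params, cs)
  line_performance(dose, sc$utp_type, pr$volume, pr$titre, pr, cs)
}

#' One-at-a-time tornado sensitivity analysis
#'
#' For each parameter, evaluates the annual dose output and the cost per
#' dose of a single production line at the low and high end of the
#' parameter's range, holding everything else at baseline, and reports the
#' percent change relative to the baseline. Rows are sorted by the largest
#' absolute effect across both outputs; purely financial parameters (prices,
#' labour, QC) have exactly zero effect on the output side.
#'
#' @param baseline A [tornado_baseline()].
#' @param ranges Named list of `c(low, high)` ranges; each range must
#'   bracket the baseline value. Defaults to [default_tornado_ranges()].
#' @return A data frame of class `tornado_table` with columns `parameter`,
#'   `low_value`, `high_value`, `delta_doses_low`, `delta_doses_high`,
#'   `delta_cost_low`, `delta_cost_high`, `max_abs_effect` (all deltas in
#'   percent).
#' @examples
#' head(tornado(), 3)  # RNA per dose ranks first
#' @export
tornado <- function(baseline = tornado_baseline(),
                    ranges = default_tornado_ranges(baseline)) {
  base_vals <- c(
    rna_per_dose = baseline$scenario$rna_per_dose,
    volume = baseline$process$volume,
    titre = baseline$process$titre,
    failure_rate = baseline$process$failure_rate,
    unlist(unclass(baseline$costs))
  )
  base <- line_performance(baseline$scenario$rna_per_dose,
                           baseline$scenario$utp_type,
                           baseline$process$volume, baseline$process$titre,
                           baseline$process, baseline$costs)
  rows <- lapply(names(ranges), function(p) {
    rng <- ranges[[p]]
    if (length(rng) != 2L || rng[1] > rng[2])
      stop_field(p, "range must be c(low, high) with low <= high")
    bv <- base_vals[[p]]
    if (is.null(bv) || bv < rng[1] || bv > rng[2])
      stop_field(p, sprintf("range [%g, %g] does not bracket the baseline %g",
                            rng[1], rng[2], bv))
    lo <- tornado_eval(baseline, p, rng[1])
    hi <- tornado_eval(baseline, p, rng[2])
    data.frame(
      parameter = p, low_value = rng[1], high_value = rng[2],
      delta_doses_low = 100 * (lo$annual_doses / base$annual_doses - 1),
      delta_doses_high = 100 * (hi$annual_doses / base$annual_doses - 1),
      delta_cost_low = 100 * (lo$cost_per_dose / base$cost_per_dose - 1),
      delta_cost_high = 100 * (hi$cost_per_dose / base$cost_per_dose - 1)
    )
  })
  out <- do.call(rbind, rows)
  out$max_abs_effect <- pmax(abs(out$delta_doses_low),
                             abs(out$delta_doses_high),
                             abs(out$delta_cost_low),
                             abs(out$delta_cost_high))
  out <- out[order(-out$max_abs_effect), ]
  rownames(out) <- NULL
  class(out) <- c("tornado_table", "data.frame")
  out
}

#' Horizontal-bar plot of a tornado table
#'
#' @param x A `tornado_table`.
#' @param which `"cost"` (cost per dose) or `"doses"` (annual doses).
#' @param ... Passed to [graphics::barplot()].
#' @return The tornado table, invisibly.
#' @export
plot_tornado <- function(x, which = c("cost", "doses"), ...) {
  which <- match.arg(which)
  lo <- if (which == "cost") x$delta_cost_low else x$delta_doses_low
  hi <- if (which == "cost") x$delta_cost_high else x$delta_doses_high
  ord <- order(pmax(abs(lo), abs(hi)))
  graphics::barplot(rbind(lo[ord], hi[ord]), beside = TRUE, horiz = TRUE,
                    names.arg = x$parameter[ord], las = 1,
                    xlab = sprintf("%% change in %s vs baseline",
                                   if (which == "cost") "cost per dose"
                                   else "annual doses"),
                    legend.text = c("low", "high"), ...)
  invisible(x)
}

#' Low / medium / high titre scenarios
#'
#' Re-evaluates capacity and cost for one vaccine at the baseline titre and
#' at +/- the given perturbation (default 20%, i.e. 4 / 5 / 6 g/L from a
#' 5 g/L baseline). The low scenario is the low titre (worst case: most
#' batches, facilities, cost and time); the high scenario the high titre.
#'
#' @param scenario A [vaccine_scenario()].
#' @param process A [process_params()]; the titre field is the baseline.
#' @param costs A [cost_params()].
#' @param demand A [demand_spec()].
#' @param volume Line scale, litres; defaults to the scenario's feasible
#'   scale.
#' @param perturbation Relative titre perturbation (0.2 = +/-20%).
#' @return A list of class `titre_scenarios` with elements `low`, `medium`,
#'   `high`, each containing `titre`, `capacity` ([capacity_summary()]
#'   result), `cost` ([opex_annual()] result) and `cost_per_dose`.
#' @examples
#' ts <- titre_scenarios(vaccine_presets()[["mRNA-100"]])
#' ts$low$capacity$required_batches_rounded   # 13544
#' ts$high$capacity$required_batches_rounded  # 9030
#' @export
titre_scenarios <- function(scenario, process = process_params(),
                            costs = cost_params(), demand = demand_spec(),
                            volume = scenario$feasible_scale,
                            perturbation = 0.2) {
  check_number(perturbation, "perturbation", lower = 0, upper = 1,
               strict_upper = TRUE)
  cases <- c(low = 1 - perturbation, medium = 1, high = 1 + perturbation)
  out <- lapply(names(cases), function(case) {
    pr <- unclass(process)
    pr$titre <- process$titre * cases[[case]]
    pr <- do.call(process_params, pr)
    cap <- capacity_summary(scenario, pr, demand, volume = volume)
    cost <- opex_annual(scenario, pr, costs, cap$required_batches,
                        volume = volume)
    list(titre = pr$titre, capacity = cap, cost = cost,
         cost_per_dose = cost_per_dose(cost$opex_annual,
                                       demand$annual_doses))
  })
  names(out) <- names(cases)
  structure(out, class = "titre_scenarios")
}

#' Sweep annual output and cost per dose across production scales
#'
#' Single-line performance as a function of bioreactor working volume.
#' Annual dose output grows close to linearly with scale while the cost per
#' dose decreases monotonically, which is what makes the largest
#' technologically feasible scale the economic optimum for high-dose
#' vaccines. Volumes above the 30 L scale-up feasibility limit are computed
#' but flagged with a warning.
#'
#' @param scenario A [vaccine_scenario()].
#' @param volumes Vector of working volumes, litres.
#' @param process A [process_params()].
#' @param costs A [cost_params()].
#' @return Data frame with columns `volume`, `annual_doses`,
#'   `cost_per_dose`.
#' @examples
#' scale_sweep(vaccine_presets()[["saRNA-1"]], volumes = c(1, 7, 30))
#' @export
scale_sweep <- function(scenario, volumes = c(1, 2, 5, 7, 10, 20, 30),
                        process = process_params(), costs = cost_params()) {
  if (any(volumes <= 0)) stop_field("volumes", "must be positive")
  if (any(volumes > 30))
    warning("volumes above the 30 L scale-up feasibility limit; ",
            "results are extrapolated", call. = FALSE)
  rows <- lapply(volumes, function(v) {
    perf <- line_performance(scenario$rna_per_dose, scenario$utp_type, v,
                             process$titre, process, costs)
    data.frame(volume = v, annual_doses = perf$annual_doses,
               cost_per_dose = perf$cost_per_dose)
  })
  do.call(rbind, rows)
}

#' Re-derive the effective recovery from a batch-requirement table
#'
#' Least-squares fit of a single effective recovery `r` to a table of
#' published (dose, titre, volume, required batches) rows, under the model
#' `batches = demand_mass / (volume * titre * r)`. The minimiser of the
#' squared batch-count error has the closed form `r = sum(a^2) / sum(a*b)`
#' with `a = demand_mass / (volume * titre)`. Contradictory rows are
#' reported through the residuals, never an error.
#'
#' @param table Data frame with columns `rna_per_dose` (ug), `titre` (g/L),
#'   `volume` (L), `batches`. The fixture
#'   `system.file("extdata", "printed_batch_requirements.csv", package =
#'   "rnavaxcap")` carries the published values.
#' @param demand_doses Annual dose demand behind the table (default 8e9).
#' @return List with `recovery` (fitted fraction), `residuals`
#'   (predicted - observed batches, one per row) and `table` (input with a
#'   `predicted` column).
#' @examples
#' tab <- read.csv(system.file("extdata", "printed_batch_requirements.csv",
#'                             package = "rnavaxcap"))
#' recalibrate_recovery(tab)$recovery  # ~0.4922
#' @export
recalibrate_recovery <- function(table, demand_doses = 8e9) {
  table <- as.data.frame(table)
  need <- c("rna_per_dose", "titre", "volume", "batches")
  if (!all(need %in% names(table)))
    stop_field("table", paste0("must have columns ",
                               paste(need, collapse = ", ")))
  if (nrow(table) < 1L) stop_field("table", "must have at least one row")
  a <- demand_mass_g(demand_doses, table$rna_per_dose) /
    (table$volume * table$titre)
  b <- table$batches
  r <- sum(a ^ 2) / sum(a * b)
  predicted <- a / r
  table$predicted <- predicted
  list(recovery = r, residuals = predicted - b, table = table)
}
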