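#' Installed capital cost of one production line
#'
#' Power-law equipment scaling: `capex_ref * (volume / ref_volume)^exponent`.
#' The default anchor (76.1 M USD at 30 L, exponent 0.5) reproduces the
#' published aggregate CapEx endpoints at 30 L and falls inside the published
#' 11-16.5 M USD range at 1 L.
#'
#' @param volume Working volume, litres.
#' @param capex_ref Capital cost at the reference volume, USD.
#' @param exponent Scaling exponent.
#' @param ref_volume Reference volume, litres.
#' @return Capital cost, USD.
#' @examples
#' capex_per_line(1)  # ~13.9 M USD
#' @export
capex_per_line <- function(volume, capex_ref = 7.61e7, exponent = 0.5,
                           ref_volume = 30) {
  if (any(volume <= 0)) stop_field("volume", "must be positive")
  capex_ref * (volume / ref_volume) ^ exponent
}

#' Cost of one production batch, by component
#'
#' Material charges follow a fixed batch recipe sized for the design titre:
#' each batch is fed `volume * design_titre` grams' worth of reagents
#' regardless of the titre actually realized (a lower realized titre lowers
#' conversion, not feed). Consumables follow a power law in volume anchored
#' at the reference scale; QC is a fixed fraction of labour.
#'
#' @param volume Working volume, litres.
#' @param costs A [cost_params()].
#' @param utp_type `"modified"` or `"wildtype"`; wild-type batches carry no
#'   modified-UTP charge.
#' @param design_titre Design titre of the batch recipe, g/L.
#' @return Named numeric vector with components `materials_cleancap`,
#'   `materials_modutp`, `materials_other`, `consumables`, `labour`, `qc`
#'   (USD per batch).
#' @export
batch_cost <- function(volume, costs = cost_params(),
                       utp_type = c("modified", "wildtype"),
                       design_titre = 5) {
  utp_type <- match.arg(utp_type)
  if (any(volume <= 0)) stop_field("volume", "must be positive")
  design_mass <- volume * design_titre
  labour <- costs$labour_hours_per_batch * costs$labour_rate
  c(
    materials_cleancap = design_mass * costs$cleancap_per_g_rna *
      costs$cleancap_price,
    materials_modutp = if (utp_type == "modified")
      design_mass * costs$modutp_per_g_rna * costs$mod_utp_price else 0,
    materials_other = design_mass * costs$materials_other_per_g,
    consumables = costs$consumables_per_batch_ref *
      (volume / costs$consumables_ref_volume) ^
      costs$consumables_scale_exponent,
    labour = labour,
    qc = costs$qc_fraction * labour
  )
}

#' Annual operating cost of meeting a batch requirement
#'
#' Builds the full cost result for running `required_batches` batches per
#' year at the given scale: materials, consumables, labour and QC scale with
#' the (real-valued) batch count, while the annualised capital charge uses
#' the integer facility count (straight-line depreciation of one line per
#' facility). The annual OpEx is the exact sum of the breakdown components.
#'
#' @param scenario A [vaccine_scenario()] (determines the UTP charge).
#' @param process A [process_params()].
#' @param costs A [cost_params()].
#' @param required_batches Annual batch requirement (real-valued).
#' @param volume Line scale, litres; defaults to `process$volume`.
#' @return An object of class `cost_result` with fields `capex_total`,
#'   `opex_annual`, `breakdown`, `facilities`.
#' @examples
#' sc <- vaccine_presets()[["mRNA-100"]]
#' rb <- required_batches(8e9, 100, 30, 5, effective_recovery())
#' opex_annual(sc, process_params(), cost_params(), rb)$opex_annual  # ~1.7e10
#' @export
opex_annual <- function(scenario, process = process_params(),
                        costs = cost_params(), required_batches,
                        volume = process$volume) {
  if (any(required_batches < 0))
    stop_field("required_batches", "must be nonnegative")
  anchors <- process$capacity_anchors
  fac <- facilities_required(required_batches, volume, anchors)
  line_capex <- capex_per_line(volume, costs$capex_ref, costs$capex_exponent,
                               costs$capex_ref_volume)
  bc <- batch_cost(volume, costs, scenario$utp_type, process$design_titre)
  breakdown <- c(bc * required_batches,
                 annualised_capex = fac * line_capex / costs$depreciation_years)
  structure(list(
    scenario = scenario$name,
    volume = volume,
    required_batches = required_batches,
    facilities = fac,
    capex_total = fac * line_capex,
    opex_annual = sum(breakdown),
    breakdown = breakdown
  ), class = "cost_result")
}

#' Production cost per dose
#'
#' @param opex_annual Annual operating cost (including annualised capital),
#'   USD/year.
#' @param annual_doses Doses produced per year.
#' @return USD per dose.
#' @examples
#' cost_per_dose(1.704e10, 8e9)  # 2.13 USD/dose
#' @export
cost_per_dose <- function(opex_annual, annual_doses) {
  if (any(annual_doses <= 0)) stop_field("annual_doses", "must be positive")
  if (any(opex_annual < 0)) stop_field("opex_annual", "must be nonnegative")
  opex_annual / annual_doses
}

# single-line economics: cost per dose and annual doses of one line producing
# at its own capacity (no demand, no facility ceiling -- it IS one line)
line_performance <- function(rna_per_dose, utp_type, volume, titre, process,
                             costs) {
  anchors <- process$capacity_anchors
  rec <- effective_recovery(process$nominal_recovery, process$failure_rate,
                            process$residual_loss_factor)
  b <- batches_per_year(volume, anchors)
  mass <- volume * titre * rec * b
  doses <- annual_doses(mass, rna_per_dose)
  bc <- batch_cost(volume, costs, utp_type, process$design_titre)
  opex <- sum(bc) * b +
    capex_per_line(volume, costs$capex_ref, costs$capex_exponent,
                   costs$capex_ref_volume) / costs$depreciation_years
  list(annual_doses = doses, annual_mass_g = mass,
       cost_per_dose = opex / doses, opex_annual = opex)
}

# breakdown ordering required of any calibrated cost parameter set:
#  - CleanCap is the largest per-gram materials component (all vaccines);
#  - materials is the largest OpEx component and consumables the second for
#    the four clinical vaccines (>= 1 ug/dose);
#  - consumables dominate for the 0.1 ug next-generation vaccine.
# Returns a named vector of violations (positive = violated, USD scale).
ordering_violations <- function(costs, process = process_params(),
                                demand = demand_spec(),
                                presets = vaccine_presets()) {
  rec <- effective_recovery(process$nominal_recovery, process$failure_rate,
                            process$residual_loss_factor)
  out <- c(
    cleancap_vs_modutp = costs$modutp_per_g_rna * costs$mod_utp_price -
      costs$cleancap_per_g_rna * costs$cleancap_price,
    cleancap_vs_other = costs$materials_other_per_g -
      costs$cleancap_per_g_rna * costs$cleancap_price
  )
  for (sc in presets) {
    v <- sc$feasible_scale
    rb <- required_batches(demand$annual_doses, sc$rna_per_dose, v,
                           process$titre, rec)
    cr <- opex_annual(sc, process, costs, rb, volume = v)
    b <- cr$breakdown
    materials <- b[["materials_cleancap"]] + b[["materials_modutp"]] +
      b[["materials_other"]]
    rest_max <- max(b[["labour"]], b[["qc"]], b[["annualised_capex"]])
    viol <- if (sc$rna_per_dose >= 1) {
      c(b[["consumables"]] - materials,   # materials largest
        rest_max - b[["consumables"]])    # consumables second
    } else {
      c(materials - b[["consumables"]],   # consumables predominant
        rest_max - b[["consumables"]])
    }
    names(viol) <- paste0(sc$name, c("_rank1", "_rank2"))
    out <- c(out, viol)
  }
  out
}

# fields of cost_params that calibrate_costs may fit, with box bounds.
# The stoichiometric coefficients are bounded in [0.05, 1]: effective
# coefficients above true stoichiometry absorb unmodelled material costs.
calibration_bounds <- function() {
  list(
    cleancap_per_g_rna = c(0.05, 1),
    modutp_per_g_rna = c(0.05, 1),
    materials_other_per_g = c(0, 1e5),
    consumables_per_batch_ref = c(0, 1e7),
    consumables_scale_exponent = c(0.05, 1.5),
    labour_hours_per_batch = c(1, 2000)
  )
}

#' Calibrate cost coefficients against printed operating-cost aggregates
#'
#' Fits the selected free cost coefficients by minimising the summed squared
#' relative error between modelled annual OpEx and a set of target values,
#' subject to the qualitative breakdown-ordering constraints (materials
#' largest and consumables second for clinical vaccines, consumables
#' predominant for the 0.1 ug vaccine, CleanCap largest within materials),
#' imposed through a smooth penalty. Identifiability is the caller's
#' responsibility: supply at least as many targets as free coefficients.
#'
#' @param targets A list whose elements are lists with fields `scenario` (a
#'   [vaccine_scenario()]), `opex` (target annual OpEx, USD/year), and
#'   optionally `volume` (defaults to the scenario's feasible scale) and
#'   `titre` (defaults to `process$titre`).
#' @param costs Starting [cost_params()].
#' @param process A [process_params()].
#' @param demand A [demand_spec()] fixing the annual dose demand.
#' @param free Character vector naming the coefficients to fit; see
#'   `names(calibration_bounds())` for the admissible set.
#' @param n_starts Number of optimiser restarts (jittered starting points).
#' @return A list of class `cost_calibration`: `costs` (updated parameter
#'   set), `fitted` (named vector), `residuals` (relative, one per target),
#'   `feasible` (all ordering constraints met), `active_constraints` (names
#'   of violated constraints, if any), and `objective`. Infeasible
#'   constraint systems are reported, not thrown.
#' @export
calibrate_costs <- function(targets, costs = cost_params(),
                            process = process_params(),
                            demand = demand_spec(),
                            free = c("materials_other_per_g",
                                     "consumables_per_batch_ref",
                                     "consumables_scale_exponent"),
                            n_starts = 3) {
  if (!length(targets)) stop("at least one target is required", call. = FALSE)
  bounds <- calibration_bounds()
  bad <- setdiff(free, names(bounds))
  if (length(bad))
    stop_field("free", paste0("not calibratable: ", paste(bad, collapse = ", ")))
  rec <- effective_recovery(process$nominal_recovery, process$failure_rate,
                            process$residual_loss_factor)
  tg <- lapply(targets, function(t) {
    list(scenario = t$scenario,
         opex = t$opex,
         volume = t$volume %||% t$scenario$feasible_scale,
         titre = t$titre %||% process$titre)
  })

  model_opex <- function(cs) {
    vapply(tg, function(t) {
      rb <- required_batches(demand$annual_doses, t$scenario$rna_per_dose,
                             t$volume, t$titre, rec)
      opex_annual(t$scenario, process, cs, rb, volume = t$volume)$opex_annual
    }, numeric(1))
  }
  with_params <- function(par) {
    cs <- unclass(costs)
    cs[free] <- as.list(par)
    do.call(cost_params, cs)
  }
  objective <- function(par) {
    cs <- with_params(par)
    pred <- model_opex(cs)
    obs <- vapply(tg, `[[`, numeric(1), "opex")
    resid <- (pred - obs) / obs
    viol <- ordering_violations(cs, process, demand)
    # violations are on a USD scale; normalise by the largest target
    pen <- sum(pmax(0, viol / max(obs)) ^ 2)
    sum(resid ^ 2) + 100 * pen
  }

  lower <- vapply(bounds[free], `[[`, numeric(1), 1)
  upper <- vapply(bounds[free], `[[`, numeric(1), 2)
  start0 <- pmin(pmax(unlist(unclass(costs)[free]), lower), upper)
  best <- NULL
  for (k in seq_len(n_starts)) {
    start <- if (k == 1) start0 else {
      # deterministic jitter spread across the box
      frac <- (k - 1) / n_starts
      lower + (upper - lower) * ((frac + seq_along(start0) * 0.37) %% 1)
    }
    fit <- optim(start, objective, method = "L-BFGS-B", lower = lower,
                 upper = upper, control = list(maxit = 500, factr = 1e7))
    # polish from the L-BFGS-B solution (Brent in one dimension)
    fit2 <- if (length(start0) == 1L) {
      optim(fit$par, objective, method = "Brent", lower = lower,
            upper = upper, control = list(maxit = 2000))
    } else {
      optim(fit$par, function(p) objective(pmin(pmax(p, lower), upper)),
            method = "Nelder-Mead",
            control = list(maxit = 2000, reltol = 1e-12))
    }
    fit2$par <- pmin(pmax(fit2$par, lower), upper)
    cand <- if (fit2$value < fit$value) fit2 else fit
    if (is.null(best) || cand$value < best$value) best <- cand
  }
  cs <- with_params(best$par)
  pred <- model_opex(cs)
  obs <- vapply(tg, `[[`, numeric(1), "opex")
  viol <- ordering_violations(cs, process, demand)
  active <- names(viol)[viol > 1e-6 * max(obs)]
  structure(list(
    costs = cs,
    fitted = stats::setNames(best$par, free),
    residuals = (pred - obs) / obs,
    predicted = pred,
    targets = obs,
    feasible = length(active) == 0L,
    active_constraints = active,
    objective = best$value
  ), class = "cost_calibration")
}

#' @export
print.cost_result <- function(x, ...) {
  cat(sprintf("<cost_result> %s at %g L: OpEx %.4g USD/yr, CapEx %.4g USD (%d facilities)\n",
              x$scenario, x$volume, x$opex_annual, x$capex_total,
              as.integer(x$facilities)))
  b <- sort(x$breakdown, decreasing = TRUE)
  for (nm in names(b))
    cat(sprintf("  %-18s %12.4g USD/yr (%5.1f%%)\n", nm, b[[nm]],
                100 * b[[nm]] / x$opex_annual))
  invisible(x)
}

#' @export
print.cost_calibration <- function(x, ...) {
  cat("<cost_calibration>", if (x$feasible) "feasible" else
    paste("INFEASIBLE:", paste(x$active_constraints, collapse = ", ")), "\n")
  cat("  fitted:", paste(sprintf("%s=%.6g", names(x$fitted), x$fitted),
                         collapse = ", "), "\n")
  cat("  relative residuals:",
      paste(sprintf("%.3g", x$residuals), collapse = ", "), "\n")
  invisible(x)
}
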