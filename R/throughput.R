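# Year/month/day conventions used throughout: 8760 h per year, month = year/12,
# day = year/365.
HOURS_PER_YEAR <- 8760

#' Annual batch capacity of one production line
#'
#' The number of batches one line completes per year varies with scale:
#' 471/year at 1 L down to 444/year at 30 L at the default anchors. Values at
#' intermediate volumes are linearly interpolated; beyond the outermost
#' anchors the curve is clamped (no printed anchor exists above 30 L, where
#' further scale-up is considered technologically infeasible anyway).
#'
#' @param volume Bioreactor working volume, litres. Vectorised.
#' @param anchors Capacity anchor table, see [default_capacity_anchors()].
#' @return Batches per year (numeric, same length as `volume`).
#' @examples
#' batches_per_year(c(1, 15.5, 30))
#' @export
batches_per_year <- function(volume, anchors = default_capacity_anchors()) {
  if (any(!is.finite(volume)) || any(volume <= 0))
    stop_field("volume", "must be positive")
  if (nrow(anchors) == 1L) return(rep(anchors$batches_per_year, length(volume)))
  approx(anchors$volume, anchors$batches_per_year, xout = volume,
         rule = 2)$y
}

#' Batch duration of one production line
#'
#' Linearly interpolated between anchors (41 h at 1 L, 48.2 h at 30 L by
#' default) and clamped beyond them; monotone nondecreasing in volume for the
#' default anchors.
#'
#' @inheritParams batches_per_year
#' @return Batch duration in hours.
#' @examples
#' batch_duration(c(1, 15.5, 30))
#' @export
batch_duration <- function(volume, anchors = default_capacity_anchors()) {
  if (any(!is.finite(volume)) || any(volume <= 0))
    stop_field("volume", "must be positive")
  if (nrow(anchors) == 1L) return(rep(anchors$batch_duration_h, length(volume)))
  approx(anchors$volume, anchors$batch_duration_h, xout = volume, rule = 2)$y
}

#' Effective recovery of synthesized RNA into usable drug substance
#'
#' Product of the nominal downstream recovery, the batch pass rate
#' `1 - failure_rate`, and the residual loss factor. At the defaults
#' (0.56, 0.05, 0.9252068) this is 0.49221, the value that reproduces the
#' published batch-requirement table.
#'
#' @param nominal Nominal downstream recovery fraction.
#' @param failure_rate Fraction of batches lost.
#' @param residual_loss_factor Residual loss calibration constant.
#' @return Effective recovery fraction.
#' @examples
#' effective_recovery()            # 0.49221
#' effective_recovery(0.56, 0, 1)  # no extra losses
#' @export
effective_recovery <- function(nominal = 0.56, failure_rate = 0.05,
                               residual_loss_factor = 0.9252068) {
  if (any(nominal < 0 | nominal > 1)) stop_field("nominal", "must be in [0, 1]")
  if (any(failure_rate < 0 | failure_rate > 1))
    stop_field("failure_rate", "must be in [0, 1]")
  if (any(residual_loss_factor < 0 | residual_loss_factor > 1))
    stop_field("residual_loss_factor", "must be in [0, 1]")
  nominal * (1 - failure_rate) * residual_loss_factor
}

#' Annual RNA output of one production line
#'
#' @param volume Working volume, litres.
#' @param titre RNA titre, g/L.
#' @param recovery Effective recovery fraction applied to synthesized RNA.
#' @param anchors Capacity anchor table.
#' @return A list with `per_batch_g` (usable RNA per batch, grams) and
#'   `annual_mass_g` (usable RNA per year, grams).
#' @examples
#' annual_output(30, 5, 0.56)  # 84 g/batch, 37296 g/yr
#' @export
annual_output <- function(volume, titre, recovery,
                          anchors = default_capacity_anchors()) {
  if (any(volume <= 0)) stop_field("volume", "must be positive")
  if (any(titre < 0)) stop_field("titre", "must be nonnegative")
  if (any(recovery < 0 | recovery > 1))
    stop_field("recovery", "must be in [0, 1]")
  per_batch <- volume * titre * recovery
  list(per_batch_g = per_batch,
       annual_mass_g = per_batch * batches_per_year(volume, anchors))
}

#' Convert an annual RNA mass into doses
#'
#' Doses are the produced mass divided by the RNA amount per dose; the
#' relation is exactly reciprocal in the dose.
#'
#' @param annual_mass_g RNA mass, grams/year.
#' @param rna_per_dose RNA per dose, micrograms.
#' @return Doses per year.
#' @examples
#' annual_doses(37296, 1)
#' @export
annual_doses <- function(annual_mass_g, rna_per_dose) {
  if (any(rna_per_dose <= 0)) stop_field("rna_per_dose", "must be positive")
  if (any(annual_mass_g < 0)) stop_field("annual_mass_g", "must be nonnegative")
  annual_mass_g * 1e6 / rna_per_dose
}

# demand in grams of RNA
demand_mass_g <- function(demand_doses, rna_per_dose) {
  demand_doses * rna_per_dose * 1e-6
}

#' Batches required to meet an annual dose demand
#'
#' @param demand_doses Annual demand, doses.
#' @param rna_per_dose RNA per dose, micrograms.
#' @param volume Working volume, litres.
#' @param titre RNA titre, g/L.
#' @param recovery Effective recovery fraction (use
#'   [effective_recovery()] defaults for resource sizing).
#' @return Required batches per year, real-valued; round to the nearest
#'   integer for reporting.
#' @examples
#' round(required_batches(8e9, 100, 30, 4, effective_recovery()))  # 13544
#' @export
required_batches <- function(demand_doses, rna_per_dose, volume, titre,
                             recovery) {
  if (any(demand_doses < 0)) stop_field("demand_doses", "must be nonnegative")
  if (any(rna_per_dose <= 0)) stop_field("rna_per_dose", "must be positive")
  if (any(volume <= 0) || any(titre <= 0) || any(recovery <= 0))
    stop("volume, titre and recovery must be positive", call. = FALSE)
  demand_mass_g(demand_doses, rna_per_dose) / (volume * titre * recovery)
}

#' Total bioreactor working volume required for an annual dose demand
#'
#' Total volume that must be in operation, given that each litre of capacity
#' turns over `batches_per_year(reference_volume)` batches per year. Equals
#' `required_batches(...) * reference_volume / batches_per_year(reference_volume)`.
#'
#' @inheritParams required_batches
#' @param reference_volume Line scale whose annual batch count sets the
#'   turnover, litres.
#' @param anchors Capacity anchor table.
#' @return Required total working volume, litres.
#' @examples
#' required_total_volume(8e9, 100, 4, effective_recovery(), 30)  # ~915 L
#' @export
required_total_volume <- function(demand_doses, rna_per_dose, titre, recovery,
                                  reference_volume,
                                  anchors = default_capacity_anchors()) {
  if (any(demand_doses < 0)) stop_field("demand_doses", "must be nonnegative")
  if (any(rna_per_dose <= 0)) stop_field("rna_per_dose", "must be positive")
  demand_mass_g(demand_doses, rna_per_dose) /
    (titre * recovery * batches_per_year(reference_volume, anchors))
}

#' Facilities required to run an annual batch load
#'
#' Assumes one production line per facility at the given scale; the count is
#' the ceiling of required batches over one line's annual batch capacity.
#'
#' @param required_batches Annual batch requirement (real-valued).
#' @param volume Line scale, litres.
#' @param anchors Capacity anchor table.
#' @return Integer facility count (0 when no batches are required).
#' @examples
#' facilities_required(13544.4, 30)  # 31
#' @export
facilities_required <- function(required_batches, volume,
                                anchors = default_capacity_anchors()) {
  if (any(required_batches < 0))
    stop_field("required_batches", "must be nonnegative")
  ifelse(required_batches <= 0, 0,
         ceiling(required_batches / batches_per_year(volume, anchors)))
}

#' Time for a single line to produce an annual dose demand
#'
#' @inheritParams required_batches
#' @param anchors Capacity anchor table.
#' @return Time in years (`Inf` when the output rate is zero); multiply by 12
#'   for months or 365 for days.
#' @examples
#' 12 * time_to_demand(8e9, 1, 30, 5, 0.56)  # ~2.6 months
#' @export
time_to_demand <- function(demand_doses, rna_per_dose, volume, titre, recovery,
                           anchors = default_capacity_anchors()) {
  if (any(demand_doses < 0)) stop_field("demand_doses", "must be nonnegative")
  if (any(rna_per_dose <= 0)) stop_field("rna_per_dose", "must be positive")
  out <- annual_output(volume, titre, recovery, anchors)$annual_mass_g
  mass <- demand_mass_g(demand_doses, rna_per_dose)
  ifelse(out <= 0, ifelse(mass > 0, Inf, 0), mass / out)
}

#' Derive total dose demand from a population
#'
#' @param population People to immunise.
#' @param doses_per_person Doses per person.
#' @return Total doses.
#' @examples
#' demand_from_population(7.8e9, 2)  # 15.6e9
#' @export
demand_from_population <- function(population, doses_per_person) {
  if (any(population < 0)) stop_field("population", "must be nonnegative")
  if (any(doses_per_person < 0))
    stop_field("doses_per_person", "must be nonnegative")
  population * doses_per_person
}

#' Brute-force scheduling oracle for batch capacity
#'
#' Independent check of the closed-form annual batch capacity: simulates a
#' warm (steady-state) staggered line in which one batch starts every
#' `8760 / batches_per_year(volume)` hours, then counts batch completions
#' falling inside the horizon, one completion at a time.
#'
#' @param volume Line scale, litres.
#' @param horizon_days Observation window, days.
#' @param anchors Capacity anchor table.
#' @return Number of batches completed within the horizon.
#' @examples
#' schedule_oracle(30, 365)  # 444 +/- 1
#' @export
schedule_oracle <- function(volume, horizon_days,
                            anchors = default_capacity_anchors()) {
  check_number(volume, "volume", lower = 0, strict_lower = TRUE)
  dur <- batch_duration(volume, anchors)
  check_number(horizon_days, "horizon_days", lower = dur / 24)
  cycle <- HOURS_PER_YEAR / batches_per_year(volume, anchors)
  horizon_h <- horizon_days * 24
  # steady state: completions occur every `cycle` hours; the line was already
  # running before t = 0, so the first completion lands at dur mod cycle
  t <- dur %% cycle
  n <- 0L
  while (t <= horizon_h) {
    n <- n + 1L
    t <- t + cycle
  }
  n
}

#' Capacity summary for one vaccine scenario
#'
#' Bundles the throughput arithmetic for one (vaccine, process, demand)
#' triple: per-batch and annual output of one line, the batches, total volume
#' and facilities required for the demand, and the single-line time to
#' demand. Resource sizing (batches, volumes, facilities) uses the full
#' effective recovery; the time to demand uses the nominal recovery only,
#' matching the published timeline convention (see the methods vignette for
#' why the two conventions differ).
#'
#' @param scenario A [vaccine_scenario()].
#' @param process A [process_params()]; its `volume` and `titre` are used.
#' @param demand A [demand_spec()].
#' @param volume Line scale override, litres; defaults to `process$volume`.
#' @param sizing_recovery Recovery used for resource sizing; defaults to
#'   [effective_recovery()] of the process parameters.
#' @param timeline_recovery Recovery used for the time to demand; defaults to
#'   the nominal recovery.
#' @return An object of class `capacity_result`.
#' @examples
#' cs <- capacity_summary(vaccine_presets()[["mRNA-100"]],
#'                        process_params(titre = 4))
#' cs$facilities  # 31
#' @export
capacity_summary <- function(scenario, process = process_params(),
                             demand = demand_spec(),
                             volume = process$volume,
                             sizing_recovery = effective_recovery(
                               process$nominal_recovery, process$failure_rate,
                               process$residual_loss_factor),
                             timeline_recovery = process$nominal_recovery) {
  anchors <- process$capacity_anchors
  out <- annual_output(volume, process$titre, sizing_recovery, anchors)
  doses <- annual_doses(out$annual_mass_g, scenario$rna_per_dose)
  rb <- required_batches(demand$annual_doses, scenario$rna_per_dose, volume,
                         process$titre, sizing_recovery)
  years <- time_to_demand(demand$annual_doses, scenario$rna_per_dose, volume,
                          process$titre, timeline_recovery, anchors)
  structure(list(
    scenario = scenario$name,
    volume = volume,
    titre = process$titre,
    sizing_recovery = sizing_recovery,
    timeline_recovery = timeline_recovery,
    rna_per_batch_g = out$per_batch_g,
    batches_per_year = batches_per_year(volume, anchors),
    annual_mass_g = out$annual_mass_g,
    annual_doses = doses,
    demand_doses = demand$annual_doses,
    required_batches = rb,
    required_batches_rounded = round(rb),
    required_total_volume = required_total_volume(
      demand$annual_doses, scenario$rna_per_dose, process$titre,
      sizing_recovery, volume, anchors),
    facilities = facilities_required(rb, volume, anchors),
    time_to_demand_years = years,
    time_to_demand_months = years * 12,
    time_to_demand_days = years * 365
  ), class = "capacity_result")
}

#' @export
print.capacity_result <- function(x, ...) {
  cat(sprintf("<capacity_result> %s at %g L, titre %g g/L\n", x$scenario,
              x$volume, x$titre))
  cat(sprintf("  one line: %.3g g/batch, %.4g g/yr = %.4g doses/yr\n",
              x$rna_per_batch_g, x$annual_mass_g, x$annual_doses))
  cat(sprintf("  demand %.3g doses: %d batches, %.3g L total, %d facilities\n",
              x$demand_doses, x$required_batches_rounded,
              x$required_total_volume, as.integer(x$facilities)))
  cat(sprintf("  single-line time to demand: %.1f months (%.0f days)\n",
              x$time_to_demand_months, x$time_to_demand_days))
  invisible(x)
}
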