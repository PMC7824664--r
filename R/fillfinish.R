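#' Define a fill-to-finish line
#'
#' Models multidose-pouch filling (e.g. a 15-needle modular filler running
#' three shifts): a daily pouch count, doses per pouch, an overall equipment
#' effectiveness (OEE) derating, and a days-per-month convention. The
#' defaults (116,250 pouches/day, 400 doses/pouch, 90% OEE, 30-day month)
#' give 1.2555 billion doses/month, within 2% of the published "around 1.24
#' billion"; the exact day-count convention behind the published figure is
#' not stated, so `days_per_month` is a parameter.
#'
#' @param pouches_per_day Pouches filled per day.
#' @param doses_per_pouch Doses per pouch.
#' @param oee Overall equipment effectiveness, in (0, 1].
#' @param days_per_month Operating days per month.
#' @return An object of class `fill_line`.
#' @examples
#' fill_rate(fill_line())  # ~1.26e9 doses/month
#' @export
fill_line <- function(pouches_per_day = 116250, doses_per_pouch = 400,
                      oee = 0.9, days_per_month = 30) {
  check_number(pouches_per_day, "pouches_per_day", lower = 0,
               strict_lower = TRUE)
  check_number(doses_per_pouch, "doses_per_pouch", lower = 0,
               strict_lower = TRUE)
  check_number(oee, "oee", lower = 0, upper = 1, strict_lower = TRUE)
  check_number(days_per_month, "days_per_month", lower = 0,
               strict_lower = TRUE)
  structure(list(pouches_per_day = as.numeric(pouches_per_day),
                 doses_per_pouch = as.numeric(doses_per_pouch),
                 oee = as.numeric(oee),
                 days_per_month = as.numeric(days_per_month)),
            class = "fill_line")
}

#' Monthly throughput of a fill-to-finish line
#'
#' Exactly multilinear in its four factors:
#' `pouches_per_day * doses_per_pouch * oee * days_per_month`.
#'
#' @param line A [fill_line()].
#' @return Doses filled per month.
#' @export
fill_rate <- function(line = fill_line()) {
  line$pouches_per_day * line$doses_per_pouch * line$oee *
    line$days_per_month
}

#' Identify the supply bottleneck between drug substance and filling
#'
#' @param ds_doses_per_month Drug-substance production rate, doses/month.
#' @param fill_doses_per_month Fill-to-finish rate, doses/month.
#' @return List with `stage` (`"drug_substance"`, `"fill_finish"` or
#'   `"balanced"`) and `ratio` (fill rate over DS rate; `NA` when both rates
#'   are zero).
#' @examples
#' bottleneck(3e10, fill_rate(fill_line()))  # fill-finish limits
#' @export
bottleneck <- function(ds_doses_per_month, fill_doses_per_month) {
  check_number(ds_doses_per_month, "ds_doses_per_month", lower = 0)
  check_number(fill_doses_per_month, "fill_doses_per_month", lower = 0)
  if (ds_doses_per_month == 0 && fill_doses_per_month == 0)
    return(list(stage = "balanced", ratio = NA_real_))
  ratio <- fill_doses_per_month / ds_doses_per_month
  stage <- if (fill_doses_per_month < ds_doses_per_month) "fill_finish"
  else if (fill_doses_per_month > ds_doses_per_month) "drug_substance"
  else "balanced"
  list(stage = stage, ratio = ratio)
}

#' Drug-substance versus fill-finish comparison for a set of vaccines
#'
#' Compares the maximum drug-substance production rate of a single line run
#' at the scale-up feasibility limit (30 L by default) with the throughput
#' of one filling line. The comparison deliberately uses the scale-up limit
#' rather than each vaccine's techno-economically feasible scale: the
#' bottleneck question is about the fastest DS production the platform
#' allows, and it is at the 30 L limit that the low-dose saRNA vaccines
#' outrun the filler. DS rates use the nominal recovery (timeline
#' convention).
#'
#' @param scenarios List of [vaccine_scenario()] objects.
#' @param process A [process_params()].
#' @param line A [fill_line()].
#' @param volume Scale at which DS rates are evaluated, litres.
#' @return Data frame with one row per scenario: `scenario`,
#'   `rna_per_dose`, `ds_doses_per_month`, `fill_doses_per_month`,
#'   `limiting_stage`, `ratio`.
#' @examples
#' fillfinish_report()[, c("scenario", "limiting_stage")]
#' @export
fillfinish_report <- function(scenarios = vaccine_presets(),
                              process = process_params(),
                              line = fill_line(), volume = 30) {
  fr <- fill_rate(line)
  rows <- lapply(scenarios, function(sc) {
    mass <- annual_output(volume, process$titre, process$nominal_recovery,
                          process$capacity_anchors)$annual_mass_g
    ds_month <- annual_doses(mass, sc$rna_per_dose) / 12
    bn <- bottleneck(ds_month, fr)
    data.frame(scenario = sc$name, rna_per_dose = sc$rna_per_dose,
               ds_doses_per_month = ds_month, fill_doses_per_month = fr,
               limiting_stage = bn$stage, ratio = bn$ratio)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
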