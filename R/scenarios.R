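#' Define a vaccine scenario
#'
#' A vaccine scenario fixes the properties of one RNA vaccine that matter for
#' capacity and cost modelling: how much RNA goes into a dose, how many doses
#' immunise a person, whether the construct uses modified
#' (N1-methylpseudouridine) or wild-type UTP, and the largest bioreactor
#' working volume at which a single production line for it is judged
#' techno-economically feasible (scale-up is capped at 30 L; beyond that,
#' capacity is added by scaling out to parallel lines).
#'
#' @param name Short label for the scenario.
#' @param rna_per_dose RNA mass per dose, in micrograms. Must be positive.
#' @param doses_per_person Doses needed to immunise one person (1 or 2).
#' @param utp_type `"modified"` (N1-methylpseudouridine-5'-triphosphate) or
#'   `"wildtype"`.
#' @param feasible_scale Techno-economically feasible line scale in litres of
#'   bioreactor working volume, in `[1, 30]`.
#' @return An object of class `vaccine_scenario` (a named list).
#' @examples
#' vaccine_scenario("saRNA-1", rna_per_dose = 1, utp_type = "wildtype",
#'                  feasible_scale = 7)
#' @export
vaccine_scenario <- function(name, rna_per_dose, doses_per_person = 2,
                             utp_type = c("modified", "wildtype"),
                             feasible_scale = 30) {
  utp_type <- if (length(utp_type) > 1L) utp_type[[1L]] else utp_type
  check_string(name, "name")
  check_number(rna_per_dose, "rna_per_dose", lower = 0, strict_lower = TRUE)
  if (!(length(doses_per_person) == 1L && doses_per_person %in% c(1, 2)))
    stop_field("doses_per_person", "must be 1 or 2")
  check_choice(utp_type, "utp_type", c("modified", "wildtype"))
  check_number(feasible_scale, "feasible_scale", lower = 1, upper = 30)
  structure(list(
    name = name,
    rna_per_dose = as.numeric(rna_per_dose),
    doses_per_person = as.numeric(doses_per_person),
    utp_type = utp_type,
    feasible_scale = as.numeric(feasible_scale)
  ), class = "vaccine_scenario")
}

#' Default batch-capacity anchors
#'
#' Two (volume, batches/year, batch duration) anchor points for a single
#' production line: 471 batches/year of 41 h each at 1 L, and 444 batches/year
#' of 48.2 h each at 30 L. Capacity at intermediate scales is linearly
#' interpolated; beyond the last anchor the value is held constant.
#'
#' @return A data frame with columns `volume`, `batches_per_year`,
#'   `batch_duration_h`.
#' @export
default_capacity_anchors <- function() {
  data.frame(
    volume = c(1, 30),
    batches_per_year = c(471, 444),
    batch_duration_h = c(41, 48.2)
  )
}

#' Define production process parameters
#'
#' Parameters of the drug-substance production process for one line. The
#' effective recovery of synthesized RNA into formulated drug substance is the
#' product of three factors: `nominal_recovery` (1 minus the combined
#' downstream purification and formulation losses), `1 - failure_rate`
#' (fraction of batches that pass), and `residual_loss_factor` (a calibration
#' constant absorbing losses not itemised in the aggregate data, e.g. QC
#' sampling and stream accounting; its default 0.9252068 is the least-squares
#' fit to the published batch-requirement table, giving an overall effective
#' recovery of 0.49221).
#'
#' @param volume Bioreactor working volume in litres.
#' @param titre Realized RNA titre in the production bioreactor, g/L.
#' @param nominal_recovery Downstream recovery fraction (default 0.56, i.e.
#'   44% combined downstream losses).
#' @param failure_rate Fraction of batches lost to process failure.
#' @param residual_loss_factor Residual loss calibration constant in (0, 1].
#' @param design_titre Titre the batch recipe is sized for, g/L. Reagent
#'   charges per batch are `volume * design_titre * per-gram coefficient`;
#'   deviations of the realized `titre` from this design basis change
#'   conversion, not feed.
#' @param capacity_anchors Data frame of capacity anchors, see
#'   [default_capacity_anchors()]. Must be strictly ordered by volume.
#' @return An object of class `process_params`.
#' @examples
#' process_params(volume = 30, titre = 5)
#' @export
process_params <- function(volume = 30, titre = 5, nominal_recovery = 0.56,
                           failure_rate = 0.05,
                           residual_loss_factor = 0.9252068,
                           design_titre = 5,
                           capacity_anchors = default_capacity_anchors()) {
  check_number(volume, "volume", lower = 0, strict_lower = TRUE)
  check_number(titre, "titre", lower = 0, strict_lower = TRUE)
  check_number(nominal_recovery, "nominal_recovery", lower = 0, upper = 1,
               strict_lower = TRUE)
  check_number(failure_rate, "failure_rate", lower = 0, upper = 1,
               strict_upper = TRUE)
  check_number(residual_loss_factor, "residual_loss_factor", lower = 0,
               upper = 1, strict_lower = TRUE)
  check_number(design_titre, "design_titre", lower = 0, strict_lower = TRUE)
  capacity_anchors <- as.data.frame(capacity_anchors)
  need <- c("volume", "batches_per_year", "batch_duration_h")
  if (!all(need %in% names(capacity_anchors)))
    stop_field("capacity_anchors",
               paste0("must have columns ", paste(need, collapse = ", ")))
  if (nrow(capacity_anchors) < 1L || any(diff(capacity_anchors$volume) <= 0))
    stop_field("capacity_anchors", "must be strictly ordered by volume")
  structure(list(
    volume = as.numeric(volume),
    titre = as.numeric(titre),
    nominal_recovery = as.numeric(nominal_recovery),
    failure_rate = as.numeric(failure_rate),
    residual_loss_factor = as.numeric(residual_loss_factor),
    design_titre = as.numeric(design_titre),
    capacity_anchors = capacity_anchors[need]
  ), class = "process_params")
}

#' Define cost model parameters
#'
#' Unit prices and calibrated coefficients of the CapEx/OpEx model. Reagent
#' per-gram coefficients are effective values calibrated against published
#' aggregate operating costs, not laboratory stoichiometry. Consumables and
#' capital cost scale with bioreactor volume by power laws anchored at the
#' 30 L reference scale.
#'
#' @param cleancap_price 5' cap analogue (CleanCap) purchase price, USD/g.
#' @param mod_utp_price Modified UTP purchase price, USD/g.
#' @param labour_rate Basic labour rate, USD/h.
#' @param qc_fraction Quality control cost as a fraction of labour cost.
#' @param materials_other_per_g Other raw materials (nucleotides, enzymes,
#'   lipids, buffers), USD per gram of design-basis RNA.
#' @param cleancap_per_g_rna Grams of CleanCap charged per gram of
#'   design-basis RNA (effective, calibrated).
#' @param modutp_per_g_rna Grams of modified UTP per gram of design-basis RNA
#'   (effective, calibrated; only charged for modified-UTP vaccines).
#' @param consumables_per_batch_ref Single-use consumables cost per batch at
#'   the reference volume, USD.
#' @param consumables_scale_exponent Power-law exponent for consumables cost
#'   versus volume.
#' @param consumables_ref_volume Reference volume for consumables, litres.
#' @param labour_hours_per_batch Operator hours charged per batch.
#' @param capex_ref Installed capital cost of one line at the reference
#'   volume, USD.
#' @param capex_exponent Power-law exponent for capital cost versus volume,
#'   in (0, 1].
#' @param capex_ref_volume Reference volume for CapEx, litres.
#' @param depreciation_years Straight-line depreciation period used to
#'   annualise capital cost.
#' @return An object of class `cost_params`.
#' @export
cost_params <- function(cleancap_price = 3000, mod_utp_price = 4700,
                        labour_rate = 20, qc_fraction = 0.5,
                        materials_other_per_g = 2950,
                        cleancap_per_g_rna = 1.0, modutp_per_g_rna = 0.45,
                        consumables_per_batch_ref = 340000,
                        consumables_scale_exponent = 0.45,
                        consumables_ref_volume = 30,
                        labour_hours_per_batch = 150,
                        capex_ref = 7.61e7, capex_exponent = 0.5,
                        capex_ref_volume = 30, depreciation_years = 10) {
  check_number(cleancap_price, "cleancap_price", lower = 0)
  check_number(mod_utp_price, "mod_utp_price", lower = 0)
  check_number(labour_rate, "labour_rate", lower = 0)
  check_number(qc_fraction, "qc_fraction", lower = 0)
  check_number(materials_other_per_g, "materials_other_per_g", lower = 0)
  check_number(cleancap_per_g_rna, "cleancap_per_g_rna", lower = 0)
  check_number(modutp_per_g_rna, "modutp_per_g_rna", lower = 0)
  check_number(consumables_per_batch_ref, "consumables_per_batch_ref",
               lower = 0)
  check_number(consumables_scale_exponent, "consumables_scale_exponent",
               lower = 0)
  check_number(consumables_ref_volume, "consumables_ref_volume", lower = 0,
               strict_lower = TRUE)
  check_number(labour_hours_per_batch, "labour_hours_per_batch", lower = 0)
  check_number(capex_ref, "capex_ref", lower = 0)
  check_number(capex_exponent, "capex_exponent", lower = 0, upper = 1,
               strict_lower = TRUE)
  check_number(capex_ref_volume, "capex_ref_volume", lower = 0,
               strict_lower = TRUE)
  check_number(depreciation_years, "depreciation_years", lower = 0,
               strict_lower = TRUE)
  structure(list(
    cleancap_price = as.numeric(cleancap_price),
    mod_utp_price = as.numeric(mod_utp_price),
    labour_rate = as.numeric(labour_rate),
    qc_fraction = as.numeric(qc_fraction),
    materials_other_per_g = as.numeric(materials_other_per_g),
    cleancap_per_g_rna = as.numeric(cleancap_per_g_rna),
    modutp_per_g_rna = as.numeric(modutp_per_g_rna),
    consumables_per_batch_ref = as.numeric(consumables_per_batch_ref),
    consumables_scale_exponent = as.numeric(consumables_scale_exponent),
    consumables_ref_volume = as.numeric(consumables_ref_volume),
    labour_hours_per_batch = as.numeric(labour_hours_per_batch),
    capex_ref = as.numeric(capex_ref),
    capex_exponent = as.numeric(capex_exponent),
    capex_ref_volume = as.numeric(capex_ref_volume),
    depreciation_years = as.numeric(depreciation_years)
  ), class = "cost_params")
}

#' Define annual vaccine demand
#'
#' @param annual_doses Annual drug-substance dose demand (default 8 billion,
#'   the assumed RNA-platform share of the global campaign).
#' @param population World population used when deriving demand.
#' @param doses_per_person Doses per person used when deriving demand.
#' @return An object of class `demand_spec`.
#' @examples
#' demand_spec()                          # 8 billion doses/year
#' demand_from_population(7.8e9, 2)       # 15.6 billion doses
#' @export
demand_spec <- function(annual_doses = 8e9, population = 7.8e9,
                        doses_per_person = 2) {
  check_number(annual_doses, "annual_doses", lower = 0, strict_lower = TRUE)
  check_number(population, "population", lower = 0, strict_lower = TRUE)
  if (!(length(doses_per_person) == 1L && doses_per_person %in% c(1, 2)))
    stop_field("doses_per_person", "must be 1 or 2")
  if (annual_doses > population * doses_per_person)
    stop_field("annual_doses",
               "cannot exceed population x doses_per_person")
  structure(list(
    annual_doses = as.numeric(annual_doses),
    population = as.numeric(population),
    doses_per_person = as.numeric(doses_per_person)
  ), class = "demand_spec")
}

#' The five built-in vaccine scenarios
#'
#' Returns the five vaccine scenarios studied: three conventional mRNA
#' vaccines at 100, 30 and 12 ug RNA per dose, a clinical saRNA vaccine at
#' 1 ug/dose, and a hypothetical next-generation single-dose saRNA vaccine at
#' 0.1 ug/dose. Feasible line scales are 30 L for the three mRNA vaccines,
#' 7 L for the 1 ug saRNA vaccine and 1 L for the 0.1 ug vaccine.
#'
#' @return A named list of five [vaccine_scenario()] objects.
#' @examples
#' sapply(vaccine_presets(), function(s) s$rna_per_dose)
#' @export
vaccine_presets <- function() {
  out <- list(
    vaccine_scenario("mRNA-100", 100, 2, "modified", 30),
    vaccine_scenario("mRNA-30", 30, 2, "modified", 30),
    vaccine_scenario("mRNA-12", 12, 2, "wildtype", 30),
    vaccine_scenario("saRNA-1", 1, 2, "wildtype", 7),
    vaccine_scenario("saRNA-0.1", 0.1, 1, "wildtype", 1)
  )
  names(out) <- vapply(out, `[[`, character(1), "name")
  out
}

# section constructors used by load_config
config_sections <- list(
  vaccine = vaccine_scenario,
  process = process_params,
  cost = cost_params,
  demand = demand_spec
)

#' Load a model configuration from a JSON file
#'
#' The configuration is a JSON object with up to four sections: `vaccine`,
#' `process`, `cost` and `demand`. Each section holds fields of the matching
#' constructor ([vaccine_scenario()], [process_params()], [cost_params()],
#' [demand_spec()]); omitted fields take the documented defaults and every
#' type invariant is enforced on load. Example configurations for the five
#' built-in vaccines ship under `system.file("extdata", package =
#' "rnavaxcap")`.
#'
#' @param path Path to a JSON configuration file.
#' @return A list of class `vaxcap_config` with elements `vaccine`,
#'   `process`, `cost`, `demand`.
#' @seealso [save_config()]
#' @export
load_config <- function(path) {
  check_string(path, "path")
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    stop("YAML configs are not supported in this build; use JSON",
         call. = FALSE)
  if (!file.exists(path))
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!is.list(raw)) stop("config must be a JSON object", call. = FALSE)
  unknown <- setdiff(names(raw), names(config_sections))
  if (length(unknown))
    stop(sprintf("unknown config section(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  out <- list(vaccine = NULL)
  for (section in names(config_sections)) {
    ctor <- config_sections[[section]]
    fields <- raw[[section]]
    # the vaccine section is optional: without it the built-in scenarios apply
    if (section == "vaccine" && is.null(fields)) next
    if (is.null(fields)) fields <- list()
    bad <- setdiff(names(fields), names(formals(ctor)))
    if (length(bad))
      stop(sprintf("unknown field(s) in section `%s`: %s", section,
                   paste(bad, collapse = ", ")), call. = FALSE)
    if (section == "vaccine" && is.null(fields$name))
      fields$name <- "unnamed"
    out[[section]] <- do.call(ctor, fields)
  }
  structure(out, class = "vaxcap_config")
}

#' Save a model configuration to a JSON file
#'
#' Writes all fields of all four sections, so that [load_config()] performs a
#' lossless round trip.
#'
#' @param config A `vaxcap_config` list, or a list with any of the elements
#'   `vaccine`, `process`, `cost`, `demand` (missing sections are written at
#'   their defaults).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  full <- list(
    vaccine = config$vaccine %||% vaccine_presets()[["mRNA-30"]],
    process = config$process %||% process_params(),
    cost = config$cost %||% cost_params(),
    demand = config$demand %||% demand_spec()
  )
  plain <- lapply(full, function(x) {
    x <- unclass(x)
    x
  })
  jsonlite::write_json(plain, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Draw a randomized scenario for property testing
#'
#' Generates one synthetic (vaccine, process, cost) triple emulating the
#' model's input space: RNA per dose log-uniform on \[0.1, 100\] ug (the
#' studied range spans three orders of magnitude), working volume uniform on
#' \[1, 50\] L, titre uniform on \[2, 7\] g/L and failure rate uniform on
#' \[0, 0.15\]. Cost parameters are returned at their defaults. The draw is
#' deterministic for a fixed seed and leaves the caller's random-number state
#' untouched.
#'
#' @param seed Integer seed.
#' @return A list with elements `vaccine`, `process`, `cost`.
#' @examples
#' s <- random_scenario(42)
#' s$vaccine$rna_per_dose
#' @export
random_scenario <- function(seed) {
  if (length(seed) != 1L || is.na(seed)) stop_field("seed", "must be a single integer")
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  dose <- 10 ^ runif(1, log10(0.1), log10(100))
  volume <- runif(1, 1, 50)
  titre <- runif(1, 2, 7)
  failure <- runif(1, 0, 0.15)
  dpp <- sample(c(1, 2), 1)
  utp <- sample(c("modified", "wildtype"), 1)
  list(
    vaccine = vaccine_scenario(sprintf("synthetic-%d", as.integer(seed)),
                               rna_per_dose = dose, doses_per_person = dpp,
                               utp_type = utp,
                               feasible_scale = min(volume, 30)),
    process = process_params(volume = volume, titre = titre,
                             failure_rate = failure),
    cost = cost_params()
  )
}

#' @export
print.vaccine_scenario <- function(x, ...) {
  cat(sprintf("<vaccine_scenario> %s: %g ug RNA/dose, %d dose(s)/person, %s UTP, feasible scale %g L\n",
              x$name, x$rna_per_dose, x$doses_per_person, x$utp_type,
              x$feasible_scale))
  invisible(x)
}

#' @export
print.process_params <- function(x, ...) {
  cat(sprintf("<process_params> %g L, titre %g g/L (design %g), recovery %g x (1-%g) x %g = %.5f\n",
              x$volume, x$titre, x$design_titre, x$nominal_recovery,
              x$failure_rate, x$residual_loss_factor,
              x$nominal_recovery * (1 - x$failure_rate) *
                x$residual_loss_factor))
  invisible(x)
}
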