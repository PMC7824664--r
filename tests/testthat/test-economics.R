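test_that("capital cost follows the anchored power law", {
  expect_equal(capex_per_line(30, 7.61e7, 0.5), 7.61e7)
  expect_equal(capex_per_line(4, 1e6, 0), 1e6)  # zero exponent: flat
  # at 1 L the default anchor lands inside the published 11-16.5 M range
  c1 <- capex_per_line(1)
  expect_gt(c1, 1.1e7)
  expect_lt(c1, 1.65e7)
  expect_equal(c1, 7.61e7 * sqrt(1 / 30))
  expect_error(capex_per_line(0), "volume")
})

test_that("per-batch costs split by component and respect the UTP type", {
  bc_mod <- batch_cost(30, cost_params(), "modified")
  bc_wt <- batch_cost(30, cost_params(), "wildtype")
  expect_named(bc_mod, c("materials_cleancap", "materials_modutp",
                         "materials_other", "consumables", "labour", "qc"))
  expect_equal(bc_wt[["materials_modutp"]], 0)
  expect_equal(bc_mod[-2], bc_wt[-2])
  expect_equal(bc_mod[["qc"]], 0.5 * bc_mod[["labour"]])
  # materials are charged on the design-basis recipe (volume x design titre)
  expect_equal(bc_mod[["materials_cleancap"]], 30 * 5 * 1.0 * 3000)
})

test_that("annual OpEx reproduces the published aggregate costs", {
  sc <- presets[["mRNA-100"]]
  rb <- required_batches(8e9, 100, 30, 5, rec_sizing)
  cr <- opex_annual(sc, process_params(), cost_params(), rb)
  # medium scenario ~17.04 B USD/yr (endpoint 21.3 B x 4/5), within 0.5%
  expect_equal(cr$opex_annual, 17.04e9, tolerance = 5e-3)
  expect_equal(sum(cr$breakdown), cr$opex_annual)
  expect_equal(cr$facilities, 25)
  expect_equal(cr$capex_total, 25 * capex_per_line(30))

  # low/high endpoints by inverse-titre scaling: 21.3 and 14.2 B USD/yr
  rb4 <- required_batches(8e9, 100, 30, 4, rec_sizing)
  cr4 <- opex_annual(sc, process_params(titre = 4), cost_params(), rb4)
  expect_equal(cr4$opex_annual, 21.3e9, tolerance = 5e-3)
  rb6 <- required_batches(8e9, 100, 30, 6, rec_sizing)
  cr6 <- opex_annual(sc, process_params(titre = 6), cost_params(), rb6)
  expect_equal(cr6$opex_annual, 14.2e9, tolerance = 5e-3)
  # inverse proportionality to titre within 0.5%
  expect_equal(cr4$opex_annual * 4 / 5, cr$opex_annual, tolerance = 5e-3)
  expect_equal(cr6$opex_annual * 6 / 5, cr$opex_annual, tolerance = 5e-3)

  # 0.1 ug next-generation vaccine: ~36.6 M USD/yr at 1 L
  sc5 <- presets[["saRNA-0.1"]]
  rb5 <- required_batches(8e9, 0.1, 1, 5, rec_sizing)
  cr5 <- opex_annual(sc5, process_params(volume = 1), cost_params(), rb5,
                     volume = 1)
  expect_equal(cr5$opex_annual, 36.6e6, tolerance = 0.02)
  expect_equal(cr5$facilities, 1)

  # CapEx totals bracket the published 1.57-2.36 B range at 30 L
  expect_equal(opex_annual(sc, process_params(titre = 4), cost_params(),
                           rb4)$capex_total, 31 * 7.61e7)
  expect_lt(abs(31 * 7.61e7 - 2.36e9) / 2.36e9, 0.01)
  expect_lt(abs(21 * 7.61e7 - 1.57e9) / 1.57e9, 0.02)
})

test_that("degenerate cost parameter sets behave sensibly", {
  sc <- presets[["mRNA-30"]]
  zero <- cost_params(cleancap_price = 0, mod_utp_price = 0, labour_rate = 0,
                      materials_other_per_g = 0,
                      consumables_per_batch_ref = 0)
  cr <- opex_annual(sc, process_params(), zero, 1000)
  expect_equal(cr$opex_annual, cr$breakdown[["annualised_capex"]])
  expect_equal(opex_annual(sc, process_params(), cost_params(), 0)$facilities,
               0)
})

test_that("cost per dose is a guarded quotient", {
  expect_equal(cost_per_dose(1.704e10, 8e9), 2.13)
  expect_equal(cost_per_dose(0, 10), 0)
  expect_equal(cost_per_dose(2 * 1.704e10, 2 * 8e9),
               cost_per_dose(1.704e10, 8e9))  # scale invariance
  expect_error(cost_per_dose(10, 0), "annual_doses")
})

test_that("breakdown ordering holds at the defaults for all five vaccines", {
  for (sc in presets) {
    v <- sc$feasible_scale
    rb <- required_batches(8e9, sc$rna_per_dose, v, 5, rec_sizing)
    b <- opex_annual(sc, process_params(volume = v), cost_params(), rb,
                     volume = v)$breakdown
    materials <- b[["materials_cleancap"]] + b[["materials_modutp"]] +
      b[["materials_other"]]
    if (sc$rna_per_dose >= 1) {
      # clinical vaccines: materials first, consumables second
      expect_gt(materials, b[["consumables"]], label = sc$name)
    } else {
      # next-generation low-dose vaccine: consumables predominant
      expect_gt(b[["consumables"]], materials, label = sc$name)
    }
    expect_gt(b[["consumables"]],
              max(b[["labour"]], b[["qc"]], b[["annualised_capex"]]),
              label = sc$name)
    # CleanCap is the largest materials component
    expect_gte(b[["materials_cleancap"]], b[["materials_modutp"]])
    expect_gte(b[["materials_cleancap"]], b[["materials_other"]])
  }
})

test_that("single-target single-coefficient calibration is an exact fit", {
  sc <- presets[["mRNA-100"]]
  target <- 1.8e10
  fit <- calibrate_costs(list(list(scenario = sc, opex = target)),
                         free = "materials_other_per_g", n_starts = 1)
  expect_true(fit$feasible)
  expect_lt(abs(fit$residuals[1]), 1e-4)
})

test_that("calibration recovers planted coefficients", {
  truth <- cost_params(materials_other_per_g = 2500,
                       consumables_per_batch_ref = 4.2e5,
                       consumables_scale_exponent = 0.6)
  targets <- lapply(presets, function(sc) {
    rb <- required_batches(8e9, sc$rna_per_dose, sc$feasible_scale, 5,
                           rec_sizing)
    list(scenario = sc,
         opex = opex_annual(sc, process_params(volume = sc$feasible_scale),
                            truth, rb,
                            volume = sc$feasible_scale)$opex_annual)
  })
  fit <- calibrate_costs(targets,
                         free = c("materials_other_per_g",
                                  "consumables_per_batch_ref",
                                  "consumables_scale_exponent"))
  expect_true(fit$feasible)
  expect_equal(unname(fit$fitted["materials_other_per_g"]), 2500,
               tolerance = 0.01)
  expect_equal(unname(fit$fitted["consumables_per_batch_ref"]), 4.2e5,
               tolerance = 0.01)
  expect_equal(unname(fit$fitted["consumables_scale_exponent"]), 0.6,
               tolerance = 0.01)
})

test_that("calibration fits both published OpEx endpoints within 2%", {
  targets <- list(
    list(scenario = presets[["mRNA-100"]], opex = 1.704e10),
    list(scenario = presets[["saRNA-0.1"]], opex = 3.66e7)
  )
  fit <- calibrate_costs(targets,
                         free = c("materials_other_per_g",
                                  "consumables_per_batch_ref",
                                  "consumables_scale_exponent"))
  expect_true(fit$feasible)
  expect_true(all(abs(fit$residuals) < 0.02))
})
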