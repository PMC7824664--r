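test_that("tornado deltas match the analytic proportionalities", {
  tt <- tornado()
  expect_s3_class(tt, "tornado_table")
  row <- function(p) tt[tt$parameter == p, ]

  # output side: pure prices cannot change the produced mass
  for (p in c("cleancap_price", "mod_utp_price", "labour_rate",
              "qc_fraction")) {
    expect_equal(row(p)$delta_doses_low, 0)
    expect_equal(row(p)$delta_doses_high, 0)
  }
  # output ~ titre
  expect_equal(row("titre")$delta_doses_low, 100 * (2 / 5 - 1))
  expect_equal(row("titre")$delta_doses_high, 100 * (7 / 5 - 1))
  # output ~ V * B(V), relative to 30 L
  expect_equal(row("volume")$delta_doses_low,
               100 * (1 * 471 / (30 * 444) - 1))
  expect_equal(row("volume")$delta_doses_high,
               100 * (50 * 444 / (30 * 444) - 1))
  # output ~ (1 - f) / (1 - 0.05)
  expect_equal(row("failure_rate")$delta_doses_low,
               100 * (1 / 0.95 - 1))
  expect_equal(row("failure_rate")$delta_doses_high,
               100 * (0.85 / 0.95 - 1))
  # reciprocal dose relation: 0.1 ug gives 300x the doses of the 30 ug baseline
  expect_equal(row("rna_per_dose")$delta_doses_low, 100 * (300 - 1))

  # ranking: dose dominates both outputs; titre outranks failure on output;
  # labour and QC have minimal cost effect
  expect_equal(tt$parameter[1], "rna_per_dose")
  expect_gt(max(abs(row("titre")[, c("delta_doses_low", "delta_doses_high")])),
            max(abs(row("failure_rate")[, c("delta_doses_low",
                                            "delta_doses_high")])))
  expect_lt(max(abs(unlist(row("labour_rate")[, c("delta_cost_low",
                                                  "delta_cost_high")]))), 1)
  expect_lt(max(abs(unlist(row("qc_fraction")[, c("delta_cost_low",
                                                  "delta_cost_high")]))), 1)
})

test_that("tornado validates that ranges bracket the baseline", {
  rng <- default_tornado_ranges()
  rng$titre <- c(6, 7)  # baseline 5 not inside
  expect_error(tornado(ranges = rng), "titre")
  rng2 <- default_tornado_ranges()
  rng2$volume <- c(50, 1)
  expect_error(tornado(ranges = rng2), "volume")
})

test_that("titre scenarios reproduce the published low/medium/high table", {
  ts <- titre_scenarios(presets[["mRNA-100"]])
  expect_equal(ts$low$capacity$required_batches_rounded, 13544)
  expect_equal(ts$high$capacity$required_batches_rounded, 9030)
  expect_lt(abs(ts$medium$capacity$required_batches - 10836), 2)
  expect_equal(ts$low$capacity$facilities, 31)
  expect_equal(ts$high$capacity$facilities, 21)

  ts5 <- titre_scenarios(presets[["saRNA-0.1"]])
  expect_equal(unname(vapply(ts5, function(x) x$capacity$facilities,
                             numeric(1))), c(1, 1, 1))

  # zero perturbation collapses the three cases
  ts0 <- titre_scenarios(presets[["mRNA-30"]], perturbation = 0)
  expect_equal(ts0$low, ts0$medium)
  expect_equal(ts0$high, ts0$medium)

  # ordering: worse titre means more batches, facilities, cost and time
  for (sc in presets) {
    t3 <- titre_scenarios(sc)
    rb <- vapply(t3, function(x) x$capacity$required_batches, numeric(1))
    fac <- vapply(t3, function(x) x$capacity$facilities, numeric(1))
    opex <- vapply(t3, function(x) x$cost$opex_annual, numeric(1))
    tim <- vapply(t3, function(x) x$capacity$time_to_demand_years,
                  numeric(1))
    doses <- vapply(t3, function(x) x$capacity$annual_doses, numeric(1))
    expect_true(all(diff(rb) < 0), label = sc$name)       # low > med > high
    expect_true(all(diff(fac) <= 0), label = sc$name)
    expect_true(all(diff(opex) < 0), label = sc$name)
    expect_true(all(diff(tim) < 0), label = sc$name)
    expect_true(all(diff(doses) > 0), label = sc$name)
  }
})

test_that("scale sweep shows linear output growth and falling cost per dose", {
  sw <- scale_sweep(presets[["saRNA-1"]], volumes = c(1, 2, 5, 7, 10, 20, 30))
  expect_true(all(diff(sw$annual_doses) > 0))
  expect_true(all(diff(sw$cost_per_dose) < 0))
  # a single 7 L line covers the 8 billion dose demand for the 1 ug vaccine
  expect_gt(sw$annual_doses[sw$volume == 7], 8e9)
  # near-linearity: doubling the volume doubles output within the ~2% bend
  # introduced by the capacity anchors
  d5 <- sw$annual_doses[sw$volume == 5]
  d10 <- sw$annual_doses[sw$volume == 10]
  expect_lt(abs(d10 / d5 - 2), 0.02 * 2)
  expect_equal(nrow(scale_sweep(presets[["mRNA-30"]], volumes = 7)), 1L)
  expect_warning(scale_sweep(presets[["mRNA-30"]], volumes = c(30, 40)),
                 "feasibility")
})

test_that("recovery recalibration fits the published batch table", {
  tab <- read.csv(system.file("extdata", "printed_batch_requirements.csv",
                              package = "rnavaxcap"))
  fit <- recalibrate_recovery(tab)
  expect_equal(fit$recovery, 0.4922, tolerance = 5e-4 / 0.4922)
  expect_length(fit$residuals, nrow(tab))
  # the fitted value is the shipped default
  expect_equal(effective_recovery(), fit$recovery, tolerance = 1e-5)
})

test_that("recovery recalibration recovers planted values", {
  # exact self-consistency on a clean table
  tab <- synthetic_batch_table(0.50, n = 5, seed = 3)
  expect_equal(recalibrate_recovery(tab)$recovery, 0.50)
  expect_equal(max(abs(recalibrate_recovery(tab)$residuals)), 0)

  # parameter recovery across 100 random tables with mild noise
  set.seed(11)
  planted <- runif(100, 0.3, 0.6)
  for (i in seq_along(planted)) {
    tab <- synthetic_batch_table(planted[i], n = 8, seed = 1000 + i,
                                 noise_sd = 0.002)
    expect_equal(recalibrate_recovery(tab)$recovery, planted[i],
                 tolerance = 0.01)
  }

  # contradictory rows: residuals reported, no exception
  bad <- data.frame(rna_per_dose = c(10, 10), titre = c(5, 5),
                    volume = c(10, 10), batches = c(1000, 2000))
  fit <- recalibrate_recovery(bad)
  expect_true(all(is.finite(fit$residuals)))
  expect_gt(max(abs(fit$residuals)), 100)
  expect_error(recalibrate_recovery(bad[0, ]), "table")
})
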