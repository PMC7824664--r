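Package: rnavaxcap
Title: Techno-Economic Capacity Model for RNA Vaccine Drug Substance
    Manufacturing
Version: 0.1.0
Authors@R:
    person("Alex", "Mercer", email = "alex.mercer@example.org",
           role = c("aut", "cre"))
Description: Batch-throughput, cost and timeline model for RNA (mRNA and
    self-amplifying RNA) vaccine drug-substance manufacturing at pandemic
    scale.  Computes annual output, required batches, total bioreactor
    working volume, facility counts and production timelines for vaccine
    scenarios spanning 0.1 to 100 micrograms of RNA per dose; a calibrated
    CapEx/OpEx model with cost-per-dose breakdowns; one-at-a-time tornado
    sensitivity analysis; scale and titre sweeps; and a fill-to-finish
    throughput comparison that identifies whether drug-substance
    production or filling limits vaccine supply.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
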