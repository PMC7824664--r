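# shared fixtures: everything is built in code at test time

`%||%` <- function(a, b) if (is.null(a)) b else a

presets <- vaccine_presets()
rec_sizing <- effective_recovery()           # 0.49221 at the defaults
demand8 <- demand_spec()                     # 8 billion doses/year

# draw n random scenarios (one per seed) as a list
draw_scenarios <- function(seeds) lapply(seeds, random_scenario)

# synthetic batch-requirement table generated from a known recovery
synthetic_batch_table <- function(recovery, n = 6, seed = 1,
                                  demand_doses = 8e9, noise_sd = 0) {
  set.seed(seed)
  dose <- 10 ^ runif(n, -1, 2)
  titre <- runif(n, 2, 7)
  volume <- runif(n, 1, 30)
  batches <- demand_doses * dose * 1e-6 / (volume * titre * recovery)
  if (noise_sd > 0) batches <- batches * exp(rnorm(n, 0, noise_sd))
  data.frame(rna_per_dose = dose, titre = titre, volume = volume,
             batches = batches)
}
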