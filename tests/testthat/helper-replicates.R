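# Shared replicate machinery for the calibration/recovery studies used by
# both the acceptance tests and scripts/acceptance.R (duplicated there so
# the script depends only on the installed package).

# Simulate one dataset and return the harmonized kept instruments.
sim_insts <- function(cfg) {
  sim <- simulate_two_sample(cfg)
  kept_instruments(harmonize(sim$exposure, sim$outcome))
}

# IVW(fixed) p-values under repeated simulation of a given config.
replicate_ivw <- function(n_rep, base_seed, ...) {
  t(vapply(seq_len(n_rep), function(r) {
    h <- sim_insts(simulation_config(..., seed = base_seed + r))
    e <- ivw(h, "fixed")
    c(beta = e$beta, p = e$pval)
  }, c(beta = 0, p = 0)))
}
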