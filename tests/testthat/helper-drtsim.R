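# shared fixtures and cached heavy runs

sd_default <- default_sequence_defs()

rc <- function(s) reverse_complement(s)

# reduced-scale spread experiment: N = 15 grid, 11,250 of each precursor
# (preserving the per-room density of the full 30 x 30 / 50,000 system),
# 6e4 steps with inoculation of ten MSPG + control protocells at the
# proportional step.  Cached so several tests can share one realization.
.run_cache <- new.env(parent = emptyenv())

reduced_fig2a <- function(seed, F_MSP = 1, P_AADE = 0.1, total = 6e4) {
  key <- paste("fig2a", seed, F_MSP, P_AADE, total, sep = "_")
  if (is.null(.run_cache[[key]])) {
    sc <- preset("fig2a", total_steps = total, n_grid = 15, totals = 11250,
                 report_every = total / 20)
    .run_cache[[key]] <- run_scenario(
      sc, params = sim_params(F_MSP = F_MSP, P_AADE = P_AADE), seed = seed)
  }
  .run_cache[[key]]
}

# a quiet one-room world with nothing in it
empty_room_world <- function(seed = 1, ...) {
  tiny_world("one_room_monomers", params = sim_params(...), seed = seed,
             np = 0, ap = 0, aap = 0)
}
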