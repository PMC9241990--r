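# Scaled-down sweeps shared across the acceptance tests (200 agents per
# simulation set; the full-size study is run by scripts/acceptance.R).
.sweep_cache <- new.env(parent = emptyenv())

acc_sweep <- function(set, n_agents = 200L, master_seed = 1L) {
  key <- sprintf("set%d_n%d_s%d", set, n_agents, master_seed)
  if (!exists(key, envir = .sweep_cache)) {
    assign(key, run_sweep(simulation_set(set, n_agents = n_agents,
                                         master_seed = master_seed)),
           envir = .sweep_cache)
  }
  get(key, envir = .sweep_cache)
}

# mean over seeds of a per-run statistic for a fixed configuration
seed_average <- function(cfg_args, sequence, n_seeds, stat) {
  vals <- vapply(seq_len(n_seeds), function(s) {
    run <- run_agent(do.call(agent_config, c(cfg_args, list(seed = s))),
                     sequence)
    stat(run)
  }, numeric(1))
  mean(vals)
}
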