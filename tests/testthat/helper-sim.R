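# shared small-scale simulation, built once per test run
.sim_cache <- new.env(parent = emptyenv())

tiny_config <- function(seed = 1, ...) {
  sim_config(seed = seed, n_cells_per_sample = 120, n_genes = 600,
             n_variants = 300, ...)
}

cached_tiny_sim <- function() {
  if (is.null(.sim_cache$sim)) {
    cfg <- tiny_config()
    .sim_cache$cfg <- cfg
    .sim_cache$sim <- simulate_counts(cfg)
    .sim_cache$vt <- simulate_variant_table(cfg)
    .sim_cache$ac <- simulate_allele_counts(.sim_cache$sim, .sim_cache$vt, cfg)
  }
  list(cfg = .sim_cache$cfg, sim = .sim_cache$sim,
       vt = .sim_cache$vt, ac = .sim_cache$ac)
}
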