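# Shared fixtures. The heavy gridded experiment suite is memoised per seed
# so the direction-of-effect and ordering tests reuse one computation.

.suite_cache <- new.env(parent = emptyenv())

suite_for_seed <- function(seed) {
  key <- paste0("seed", seed)
  if (is.null(.suite_cache[[key]])) {
    grid <- generate_forcing(forcing_spec(), seed = seed)
    .suite_cache[[key]] <- run_experiment_suite(grid)
  }
  .suite_cache[[key]]
}

footprint_of <- function(suite, experiment, pft, metric) {
  fp <- suite$footprints
  fp$area_km2[fp$experiment == experiment & fp$pft == pft & fp$metric == metric]
}

# a mid-range replete test environment (single box)
replete_env <- function(par = 20) {
  list(par = par, temperature = 5, day_fraction = 0.6,
       n = 25, p = 1.7, si = 40, d_fe = 1.0, d_mn = 1.0, d_zn = 1.0)
}

within_env <- function(env, ...) {
  mods <- list(...)
  env[names(mods)] <- mods
  env
}

mid_state <- function(p, chl_c = 0.02) {
  list(biomass_c = 1, q_n = 0.12, q_p = 0.008,
       q_si = if (p$name == "diatom") 0.1 else NA_real_,
       q_fe = 10, q_mn = 2, q_zn = 5, chl_c = chl_c)
}
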