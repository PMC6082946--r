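# Shared fixtures: memoised simulation runs so several test files can
# reuse the same (seed, protocol) realizations without re-simulating.

.run_cache <- new.env(parent = emptyenv())

cached_run <- function(key, config) {
  if (!exists(key, envir = .run_cache))
    assign(key, run_simulation(config), envir = .run_cache)
  get(key, envir = .run_cache)
}

fig2_run <- function(seed) {
  cached_run(paste0("fig2_", seed),
             simulation_config(figure2_schedule(), master_seed = seed))
}

fig5_run <- function(seed) {
  cached_run(paste0("fig5_", seed),
             simulation_config(figure5_schedule(), master_seed = seed))
}

# A tiny deterministic population for scalar-level neuron tests.
rs_population <- function(n = 1L) {
  structure(list(a = rep(0.02, n), b = rep(0.2, n), c = rep(-65, n),
                 d = rep(8, n), r = rep(0, n),
                 is_excitatory = rep(TRUE, n), n_exc = n, n_inh = 0L),
            class = "neuron_population")
}

# Normal warm-up followed by acute exposure (the acute measurement
# protocol for the synchronized-fraction statistic).
acute_after_warmup <- function(seed) {
  cached_run(paste0("acute_", seed), simulation_config(
    make_schedule(list(
      list(t_start_ms = 0, t_end_ms = 1000,
           params = mode_parameters("normal"), label = "warmup"),
      list(t_start_ms = 1000, t_end_ms = 2000,
           params = mode_parameters("acute"), label = "acute"))),
    master_seed = seed))
}

# Spikes of a result restricted to [t0_ms, t1_ms), re-zeroed.
window_raster <- function(result, t0_ms, t1_ms) {
  k <- result$raster$time_ms >= t0_ms & result$raster$time_ms < t1_ms
  r <- result$raster[k, , drop = FALSE]
  r$time_ms <- r$time_ms - t0_ms
  r
}
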