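#' Specification for a synthetic spike raster
#'
#' @param n_neurons number of neurons.
#' @param duration_ms raster duration.
#' @param base_rate_hz mean firing rate per neuron.
#' @param modulation_freq_hz sinusoidal rate-modulation frequency
#'   (`NULL` = unmodulated).
#' @param modulation_depth modulation depth in `[0, 1]`.
#' @param coincidence_fraction fraction of neurons sharing identical
#'   spike times, in `[0, 1]`.
#' @param seed integer seed.
#' @return object of class `synthetic_raster_spec`.
#' @export
synthetic_raster_spec <- function(n_neurons, duration_ms, base_rate_hz,
                                  modulation_freq_hz = NULL,
                                  modulation_depth = 0,
                                  coincidence_fraction = 0,
                                  seed = 1L) {
  stopifnot(base_rate_hz >= 0,
            modulation_depth >= 0, modulation_depth <= 1,
            coincidence_fraction >= 0, coincidence_fraction <= 1)
  structure(list(n_neurons = as.integer(n_neurons),
                 duration_ms = duration_ms,
                 base_rate_hz = base_rate_hz,
                 modulation_freq_hz = modulation_freq_hz,
                 modulation_depth = modulation_depth,
                 coincidence_fraction = coincidence_fraction,
                 seed = as.integer(seed)),
            class = "synthetic_raster_spec")
}

# One homogeneous Poisson spike train on [0, T) ms at rate_hz.
poisson_train <- function(rate_hz, duration_ms) {
  n <- rpois(1, rate_hz * duration_ms / 1000)
  sort(runif(n, 0, duration_ms))
}

# Inhomogeneous Poisson train by thinning: candidates at the rate
# ceiling are kept with probability rate(t) / rate_max, which makes the
# construction exact and independent of any binning.
thinned_train <- function(base_rate_hz, depth, freq_hz, duration_ms) {
  rate_max <- base_rate_hz * (1 + depth)
  if (rate_max == 0) return(numeric(0))
  cand <- poisson_train(rate_max, duration_ms)
  if (length(cand) == 0) return(cand)
  rate <- base_rate_hz * (1 + depth * sin(2 * pi * freq_hz * cand / 1000))
  cand[runif(length(cand)) < rate / rate_max]
}

raster_from_trains <- function(trains, floor_ms = TRUE) {
  times <- unlist(trains)
  ids <- rep(seq_along(trains) - 1L,
             vapply(trains, length, integer(1)))
  if (floor_ms) times <- floor(times)
  o <- order(times, ids)
  data.frame(time_ms = times[o], neuron_id = ids[o],
             is_excitatory = rep(TRUE, length(times)))
}

#' Independent Poisson spike raster
#'
#' Homogeneous Poisson spikes per neuron at `base_rate_hz`; spike times
#' are floored to 1-ms resolution to match the simulator's raster
#' format. Deterministic per seed.
#'
#' @param spec a [synthetic_raster_spec()].
#' @return raster data.frame (`time_ms`, `neuron_id`, `is_excitatory`).
#' @export
poisson_raster <- function(spec) {
  with_seed(spec$seed, raster_from_trains(
    lapply(seq_len(spec$n_neurons), function(i)
      poisson_train(spec$base_rate_hz, spec$duration_ms))))
}

#' Rhythmically modulated raster with optional coincident subpopulation
#'
#' Each neuron is an inhomogeneous Poisson process with rate
#' `base * (1 + depth * sin(2 pi f t))`, generated by thinning. The
#' first `ceiling(coincidence_fraction * n)` neurons share one common
#' spike train drawn from the same process, producing perfectly
#' coincident population events; the rest are independent.
#'
#' @param spec a [synthetic_raster_spec()] with `modulation_freq_hz`
#'   set (0 allowed, meaning unmodulated).
#' @return raster data.frame.
#' @export
rhythmic_raster <- function(spec) {
  freq <- if (is.null(spec$modulation_freq_hz)) 0 else
    spec$modulation_freq_hz
  with_seed(spec$seed, {
    n_coinc <- ceiling(spec$coincidence_fraction * spec$n_neurons)
    shared <- if (n_coinc > 0)
      thinned_train(spec$base_rate_hz, spec$modulation_depth, freq,
                    spec$duration_ms) else numeric(0)
    trains <- lapply(seq_len(spec$n_neurons), function(i) {
      if (i <= n_coinc) shared else
        thinned_train(spec$base_rate_hz, spec$modulation_depth, freq,
                      spec$duration_ms)
    })
    raster_from_trains(trains)
  })
}
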