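#' Build a simulation configuration
#'
#' Gathers everything one run needs: a protocol schedule, the population
#' sizes, the master seed (from which the four named RNG streams are
#' derived, see [derive_stream_seeds()]), astrocyte parameters and
#' initial conditions, and behavioural switches.
#'
#' @param schedule a `schedule` object or a canonical schedule name
#'   accepted by [named_schedule()].
#' @param master_seed integer master seed.
#' @param n_exc,n_inh population sizes (defaults 800 / 200).
#' @param dt_ms outer integration step in ms (default 1); must divide all
#'   segment boundaries.
#' @param astro an `astro_parameters` object.
#' @param astro_init an `astro_state` giving initial conditions
#'   (default `(c, ce, sm, gm) = (0.1, 1, 0, 0)`).
#' @param astro_targets `"all"` to add the gliotransmitter current to
#'   every neuron, `"excitatory"` to restrict it.
#' @param noise_shared if `TRUE`, all excitatory neurons share one noise
#'   draw per step and all inhibitory neurons another; default `FALSE`
#'   (independent per-neuron draws).
#' @param record_astro record the astrocyte trace (default `TRUE`).
#' @return a `simulation_config` object.
#' @export
simulation_config <- function(schedule, master_seed = 1L,
                              n_exc = 800L, n_inh = 200L, dt_ms = 1,
                              astro = astro_parameters(),
                              astro_init = astro_state(),
                              astro_targets = c("all", "excitatory"),
                              noise_shared = FALSE,
                              record_astro = TRUE) {
  if (is.character(schedule)) schedule <- named_schedule(schedule)
  stopifnot(inherits(schedule, "schedule"))
  astro_targets <- match.arg(astro_targets)
  bounds <- c(vapply(schedule$segments, `[[`, numeric(1), "t_start_ms"),
              schedule$total_duration_ms)
  if (any(abs(bounds / dt_ms - round(bounds / dt_ms)) > 1e-9))
    stop("dt_ms must divide every segment boundary")
  structure(list(schedule = schedule, master_seed = as.integer(master_seed),
                 n_exc = as.integer(n_exc), n_inh = as.integer(n_inh),
                 dt_ms = dt_ms, astro = astro, astro_init = astro_init,
                 astro_targets = astro_targets,
                 noise_shared = noise_shared,
                 record_astro = record_astro),
            class = "simulation_config")
}

#' Run one coupled network-astrocyte simulation
#'
#' Executes the protocol schedule segment by segment. Within a segment,
#' each outer step adds the synaptic current of the previous step's
#' spikes, the noisy mode-dependent external drive, and the uniform
#' gliotransmitter current `k_glio * glio_release_scale * delta * Gm`;
#' advances the neurons (two voltage half-steps, one recovery step,
#' threshold/reset at 30 mV); then advances the astrocyte by one 1-ms
#' Euler step driven by its dedicated noise stream. The weight matrix is
#' rebuilt from the fixed connectivity realization whenever a segment
#' changes `s_exc` or `s_inh`, so weight interventions act on the same
#' network. All noise is pre-drawn per stream for the full run, which
#' makes recorded activity before a segment invariant to changes in that
#' segment's parameters.
#'
#' @param config a `simulation_config`.
#' @return a `simulation_result`: list with `raster` (data.frame
#'   `time_ms`, `neuron_id` 0-based, `is_excitatory`), `psc` (integer
#'   spike counts per outer step), `astro_trace` (data.frame `time_s`,
#'   `c`, `ce`, `sm`, `gm`, `i_astro`), `duration_ms`, `config`, and the
#'   resolved stream `seeds`.
#' @export
run_simulation <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  sched <- config$schedule
  n <- config$n_exc + config$n_inh
  seeds <- derive_stream_seeds(config$master_seed)
  total_steps <- as.integer(round(sched$total_duration_ms / config$dt_ms))

  if (total_steps == 0L) {
    return(structure(list(
      raster = data.frame(time_ms = numeric(0), neuron_id = integer(0),
                          is_excitatory = logical(0)),
      psc = integer(0),
      astro_trace = data.frame(time_s = numeric(0), c = numeric(0),
                               ce = numeric(0), sm = numeric(0),
                               gm = numeric(0), i_astro = numeric(0)),
      duration_ms = 0, config = config, seeds = seeds),
      class = "simulation_result"))
  }

  pop <- init_population(config$n_exc, config$n_inh,
                         seed = seeds[["heterogeneity"]])
  first_mode <- sched$segments[[1]]$params
  conn <- init_connectivity(config$n_exc, config$n_inh,
                            seed = seeds[["connectivity"]],
                            s_exc = first_mode$s_exc,
                            s_inh = first_mode$s_inh)
  noise <- with_seed(seeds[["noise"]],
                     matrix(rnorm(n * total_steps), nrow = n))
  astro_noise <- with_seed(seeds[["astro"]], rnorm(total_steps))

  v <- rep(-65, n); u <- pop$b * v
  fired <- rep(FALSE, n)
  ast <- with(config$astro_init, c(c, ce, sm, gm))
  ap <- astro_pars_vec(config$astro)

  sp_t <- list(); sp_id <- list(); psc <- integer(0)
  atr <- list()
  for (s in sched$segments) {
    p <- s$params
    if (p$s_exc != conn$s_exc || p$s_inh != conn$s_inh)
      conn <- rescale_weights(conn, p$s_exc, p$s_inh)
    i0 <- as.integer(round(s$t_start_ms / config$dt_ms)) + 1L
    i1 <- as.integer(round(s$t_end_ms / config$dt_ms))
    out <- sim_segment_cpp(
      v, u, pop$a, pop$b, pop$c, pop$d, conn$S,
      noise[, i0:i1, drop = FALSE], astro_noise[i0:i1], fired, ast,
      config$n_exc, p$k_exc, p$k_inh, p$delta,
      config$astro$k_glio * p$glio_release_scale,
      config$dt_ms, config$dt_ms / 1000, as.integer(s$t_start_ms), ap,
      config$astro_targets == "excitatory", config$noise_shared,
      config$record_astro)
    v <- out$v; u <- out$u; fired <- out$fired; ast <- out$astro_state
    sp_t[[length(sp_t) + 1L]] <- out$spike_time_ms
    sp_id[[length(sp_id) + 1L]] <- out$spike_id
    psc <- c(psc, out$psc)
    if (config$record_astro) atr[[length(atr) + 1L]] <- out$astro_trace
  }

  ids <- unlist(sp_id)
  raster <- data.frame(time_ms = as.numeric(unlist(sp_t)) * config$dt_ms,
                       neuron_id = ids,
                       is_excitatory = ids < config$n_exc)
  astro_trace <- if (config$record_astro) {
    at <- do.call(rbind, atr)
    data.frame(time_s = (seq_len(total_steps) - 1) * config$dt_ms / 1000,
               c = at[, 1], ce = at[, 2], sm = at[, 3], gm = at[, 4],
               i_astro = at[, 5])
  } else NULL

  structure(list(raster = raster, psc = psc, astro_trace = astro_trace,
                 duration_ms = sched$total_duration_ms, config = config,
                 seeds = seeds),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat("<simulation_result>", x$duration_ms, "ms,",
      x$config$n_exc + x$config$n_inh, "neurons,",
      nrow(x$raster), "spikes, seed", x$config$master_seed, "\n")
  invisible(x)
}

#' Sweep one mode or astrocyte parameter across simulations
#'
#' Runs one 1-segment simulation per (value, seed) pair, holding the
#' connectivity and noise realizations fixed per seed across values
#' (stream discipline guarantees this), and evaluates a metric on each
#' result. Used to locate intervention thresholds, e.g. the excitatory
#' drive reduction at which chronic-mode synchrony collapses.
#'
#' @param base_mode a `mode_parameters` giving the held-fixed parameters.
#' @param parameter path of the scalar to vary: one of `"mode.k_exc"`,
#'   `"mode.k_inh"`, `"mode.s_exc"`, `"mode.s_inh"`, `"mode.delta"`,
#'   `"mode.glio_release_scale"`, or `"astro.k_glio"`.
#' @param values numeric vector of parameter values, in sweep order.
#' @param metric function of a `simulation_result` returning one number,
#'   or one of the built-in names `"synchrony"` (synchrony index of the
#'   PSC) and `"dominant_freq"` (dominant frequency, 1-100 Hz).
#' @param seeds integer vector of master seeds (one simulation per seed
#'   per value).
#' @param duration_ms duration of each run (default 1000).
#' @param astro base `astro_parameters` (its `k_glio` is the value being
#'   swept when `parameter = "astro.k_glio"`).
#' @param ... further arguments passed to [simulation_config()].
#' @return data.frame with columns `value`, `seed`, `metric`.
#' @export
sweep_parameter <- function(base_mode, parameter, values,
                            metric = "synchrony", seeds = 1L,
                            duration_ms = 1000,
                            astro = astro_parameters(), ...) {
  valid <- c("mode.k_exc", "mode.k_inh", "mode.s_exc", "mode.s_inh",
             "mode.delta", "mode.glio_release_scale", "astro.k_glio")
  if (!parameter %in% valid)
    stop("unknown parameter path '", parameter, "'; valid paths: ",
         paste(valid, collapse = ", "))
  metric_fn <- if (is.function(metric)) metric else switch(
    metric,
    synchrony = function(res) synchrony_index(res$psc),
    dominant_freq = function(res) {
      spec <- psc_spectrogram(res$psc)
      dominant_frequency(spec)
    },
    stop("unknown metric '", metric, "'"))

  grid <- expand.grid(seed = seeds, value = values)
  base_astro <- astro
  met <- mapply(function(seed, value) {
    mode <- base_mode
    astro <- base_astro
    if (parameter == "astro.k_glio") {
      astro$k_glio <- value
    } else {
      field <- sub("^mode\\.", "", parameter)
      mode[[field]] <- value
    }
    cfg <- simulation_config(constant_schedule(mode, duration_ms),
                             master_seed = seed, astro = astro, ...)
    metric_fn(run_simulation(cfg))
  }, grid$seed, grid$value)
  data.frame(value = grid$value, seed = grid$seed, metric = met)
}

#' First sweep value crossing a threshold
#'
#' Aggregates a [sweep_parameter()] table over seeds (median) and
#' returns the first value, in sweep order, whose aggregated metric
#' falls below (`direction = "below"`) or rises above
#' (`direction = "above"`) the threshold. `NA` if no value crosses.
#'
#' @param sweep_df data.frame from [sweep_parameter()].
#' @param threshold numeric criterion.
#' @param direction `"below"` or `"above"`.
#' @return the crossing value, or `NA`.
#' @export
first_crossing <- function(sweep_df, threshold,
                           direction = c("below", "above")) {
  direction <- match.arg(direction)
  vals <- unique(sweep_df$value)  # preserves sweep order
  agg <- vapply(vals, function(v) {
    stats::median(sweep_df$metric[sweep_df$value == v])
  }, numeric(1))
  hit <- if (direction == "below") agg < threshold else agg > threshold
  if (!any(hit)) return(NA_real_)
  vals[which(hit)[1]]
}
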