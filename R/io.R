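#' Write a spike raster to CSV
#'
#' Header `time_ms,neuron_id,is_excitatory`; times at outer-step
#' resolution, 0-based neuron ids, `is_excitatory` as `TRUE`/`FALSE`.
#'
#' @param raster raster data.frame.
#' @param path output path.
#' @export
write_raster_csv <- function(raster, path) {
  write.csv(raster[, c("time_ms", "neuron_id", "is_excitatory")], path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a spike raster from CSV
#'
#' @param path CSV path as written by [write_raster_csv()].
#' @return raster data.frame.
#' @export
read_raster_csv <- function(path) {
  x <- read.csv(path)
  need <- c("time_ms", "neuron_id", "is_excitatory")
  if (!all(need %in% names(x)))
    stop("raster CSV must have columns ", paste(need, collapse = ", "))
  x$neuron_id <- as.integer(x$neuron_id)
  x$is_excitatory <- as.logical(x$is_excitatory)
  x[, need]
}

#' Write a population spike count series to CSV
#'
#' Header `time_ms,count`.
#'
#' @param psc integer spike-count vector (1-ms bins unless `bin_ms`
#'   says otherwise).
#' @param path output path.
#' @param bin_ms bin width (default 1).
#' @export
write_psc_csv <- function(psc, path, bin_ms = 1) {
  write.csv(data.frame(time_ms = (seq_along(psc) - 1) * bin_ms,
                       count = psc),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an astrocyte trace to CSV
#'
#' Header `time_s,c,ce,Sm,Gm,I_astro`.
#'
#' @param astro_trace data.frame from [run_simulation()].
#' @param path output path.
#' @export
write_astro_trace_csv <- function(astro_trace, path) {
  out <- astro_trace
  names(out) <- c("time_s", "c", "ce", "Sm", "Gm", "I_astro")
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a run manifest (config echo, seeds, version)
#'
#' @param result a `simulation_result`.
#' @param path output JSON path.
#' @export
write_run_manifest <- function(result, path) {
  cfg <- result$config
  jsonlite::write_json(list(
    package_version = as.character(utils::packageVersion("gliosim")),
    master_seed = cfg$master_seed,
    stream_seeds = as.list(result$seeds),
    n_exc = cfg$n_exc, n_inh = cfg$n_inh, dt_ms = cfg$dt_ms,
    k_glio = cfg$astro$k_glio, astro_targets = cfg$astro_targets,
    noise_shared = cfg$noise_shared,
    schedule = schedule_to_list(cfg$schedule)
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
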