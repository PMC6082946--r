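#' Derive independent named RNG stream seeds from one master seed
#'
#' A simulation draws from four conceptually independent random sources:
#' per-neuron parameter heterogeneity, connectivity weights, per-step neuron
#' noise, and the astrocyte drive signal. Giving each its own derived seed
#' means that, for a fixed master seed, regenerating one source never
#' perturbs the draws of another (e.g. rescaling synaptic weights mid-run
#' reuses the identical connectivity realization).
#'
#' @param master_seed single integer master seed.
#' @return named integer vector with elements `heterogeneity`,
#'   `connectivity`, `noise`, `astro`, each in `[1, 2^31 - 2]`.
#' @export
derive_stream_seeds <- function(master_seed) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L,
            is.finite(master_seed))
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(master_seed))
  seeds <- sample.int(2147483646L, 4L)
  names(seeds) <- c("heterogeneity", "connectivity", "noise", "astro")
  seeds
}

# Evaluate `expr` under a temporary seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}
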