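#' Initialize a heterogeneous Izhikevich neuron population
#'
#' Builds per-neuron Izhikevich parameters for a mixed
#' excitatory/inhibitory cortical population. Each neuron carries one
#' uniform heterogeneity draw `r` in `[0, 1]`. Excitatory (regular-spiking
#' to chattering) neurons use `a = 0.02`, `b = 0.2`,
#' `c = -65 + 15 r^2` mV, `d = 8 - 6 r^2`; inhibitory (fast-spiking to
#' low-threshold) neurons use `a = 0.02 + 0.08 r`, `b = 0.25 - 0.05 r`,
#' `c = -65` mV, `d = 2`. Excitatory neurons occupy indices
#' `1..n_exc`, inhibitory neurons follow.
#'
#' @param n_exc number of excitatory neurons (default 800).
#' @param n_inh number of inhibitory neurons (default 200).
#' @param seed integer seed for the heterogeneity draws.
#' @return object of class `neuron_population`: list with vectors `a`, `b`,
#'   `c`, `d`, `r`, logical `is_excitatory`, and counts `n_exc`, `n_inh`.
#' @export
init_population <- function(n_exc = 800L, n_inh = 200L, seed = 1L) {
  n_exc <- as.integer(n_exc); n_inh <- as.integer(n_inh)
  if (n_exc < 0L || n_inh < 0L || n_exc + n_inh < 1L)
    stop("population sizes must be nonnegative with at least one neuron")
  n <- n_exc + n_inh
  r <- with_seed(seed, runif(n))
  is_exc <- c(rep(TRUE, n_exc), rep(FALSE, n_inh))
  a <- ifelse(is_exc, 0.02, 0.02 + 0.08 * r)
  b <- ifelse(is_exc, 0.2, 0.25 - 0.05 * r)
  cc <- ifelse(is_exc, -65 + 15 * r^2, -65)
  d <- ifelse(is_exc, 8 - 6 * r^2, 2)
  structure(list(a = a, b = b, c = cc, d = d, r = r,
                 is_excitatory = is_exc, n_exc = n_exc, n_inh = n_inh),
            class = "neuron_population")
}

#' Initialize random synaptic connectivity
#'
#' Draws dense uniform `[0, 1]` connectivity matrices `g1`
#' (`n x n_exc`, excitatory source columns) and `g2` (`n x n_inh`,
#' inhibitory source columns) and assembles the signed weight matrix
#' `S = [s_exc * g1, s_inh * g2]` (rows index postsynaptic targets,
#' columns presynaptic sources). The raw `g1`, `g2` are retained so the
#' weight scales can be changed later without redrawing the connectivity
#' realization (see [rescale_weights()]); this is what makes within-run
#' weight interventions exactly comparable. Self-connections are permitted.
#'
#' @param n_exc,n_inh population sizes.
#' @param seed integer seed for the connectivity draws.
#' @param s_exc excitatory weight scale (default 0.5).
#' @param s_inh inhibitory weight scale, nonpositive (default -1).
#' @return object of class `synaptic_matrix`: list with `S`, `g1`, `g2`,
#'   `s_exc`, `s_inh`, `n_exc`, `n_inh`.
#' @export
init_connectivity <- function(n_exc = 800L, n_inh = 200L, seed = 1L,
                              s_exc = 0.5, s_inh = -1) {
  n_exc <- as.integer(n_exc); n_inh <- as.integer(n_inh)
  if (n_exc < 0L || n_inh < 0L || n_exc + n_inh < 1L)
    stop("population sizes must be nonnegative with at least one neuron")
  n <- n_exc + n_inh
  gs <- with_seed(seed, {
    g1 <- matrix(runif(n * n_exc), nrow = n, ncol = n_exc)
    g2 <- matrix(runif(n * n_inh), nrow = n, ncol = n_inh)
    list(g1 = g1, g2 = g2)
  })
  sm <- structure(list(S = NULL, g1 = gs$g1, g2 = gs$g2,
                       s_exc = s_exc, s_inh = s_inh,
                       n_exc = n_exc, n_inh = n_inh),
                  class = "synaptic_matrix")
  rescale_weights(sm, s_exc, s_inh)
}

#' Rescale synaptic weight blocks without redrawing connectivity
#'
#' @param sm a `synaptic_matrix`.
#' @param s_exc,s_inh new weight scales (defaults keep current values).
#' @return the `synaptic_matrix` with `S` rebuilt from the stored `g1`, `g2`.
#' @export
rescale_weights <- function(sm, s_exc = sm$s_exc, s_inh = sm$s_inh) {
  stopifnot(inherits(sm, "synaptic_matrix"))
  sm$s_exc <- s_exc
  sm$s_inh <- s_inh
  sm$S <- cbind(s_exc * sm$g1, s_inh * sm$g2)
  sm
}

#' Synaptic input current from the most recent spikes
#'
#' `I_syn[i]` is the sum of `S[i, j]` over presynaptic neurons `j` that
#' fired, i.e. each spike deposits its full signed weight onto every
#' target for one time step (instantaneous current-based synapses, no
#' delays or kinetics).
#'
#' @param sm a `synaptic_matrix`, or a plain numeric weight matrix.
#' @param fired logical vector, one flag per source neuron.
#' @return numeric vector of per-target currents.
#' @export
synaptic_current <- function(sm, fired) {
  S <- if (inherits(sm, "synaptic_matrix")) sm$S else sm
  if (length(fired) != ncol(S))
    stop("`fired` must have one flag per source neuron (", ncol(S), ")")
  fired <- as.logical(fired)
  if (!any(fired)) return(numeric(nrow(S)))
  rowSums(S[, fired, drop = FALSE])
}

#' Noisy mode-dependent external drive
#'
#' Each excitatory neuron receives `delta * K_exc * f1_i` and each
#' inhibitory neuron `delta * K_inh * f2_i`, where `f1`, `f2` are standard
#' normal draws (one per neuron per step by default) and `delta` is the
#' astrocytic transporter-activity attenuation in `[0.5, 1]`.
#'
#' @param mode a [mode_parameters()] object (fields `k_exc`, `k_inh`,
#'   `delta`).
#' @param f1 standard-normal draws for the excitatory neurons.
#' @param f2 standard-normal draws for the inhibitory neurons.
#' @return numeric vector of per-neuron external currents, excitatory
#'   entries first.
#' @export
external_current <- function(mode, f1, f2) {
  c(mode$delta * mode$k_exc * f1, mode$delta * mode$k_inh * f2)
}

#' Initialize the network dynamical state
#'
#' Membrane voltage starts at the common resting value -65 mV with the
#' recovery variable at its nullcline `u = b * v`.
#'
#' @param pop a `neuron_population`.
#' @return object of class `network_state`: list with `v`, `u`, logical
#'   `fired`, and time `t` (ms).
#' @export
init_state <- function(pop) {
  v <- rep(-65, pop$n_exc + pop$n_inh)
  structure(list(v = v, u = pop$b * v,
                 fired = rep(FALSE, length(v)), t = 0),
            class = "network_state")
}

#' Advance the neuron population by one outer time step
#'
#' Forward-Euler update of the Izhikevich equations
#' `v' = 0.04 v^2 + 5 v + 140 - u + I` and `u' = a (b v - u)`.
#' The voltage equation is advanced in two half-steps of `dt/2` for
#' numerical stability (the standard convention for this model family)
#' while `u` is advanced once per outer step. Neurons whose voltage
#' reaches 30 mV are flagged as fired, then reset: `v <- c_i`,
#' `u <- u + d_i`.
#'
#' This is the reference scalar/vector implementation; [run_simulation()]
#' executes the identical scheme in compiled code.
#'
#' @param state a `network_state`.
#' @param pop a `neuron_population`.
#' @param I_total per-neuron total input current (synaptic + external +
#'   astrocytic), held constant across the two half-steps.
#' @param dt outer step in ms (default 1).
#' @return updated `network_state` with `fired` marking this step's spikes.
#' @export
step_neurons <- function(state, pop, I_total, dt = 1) {
  v <- state$v; u <- state$u
  for (k in 1:2)
    v <- v + (dt / 2) * (0.04 * v^2 + 5 * v + 140 - u + I_total)
  u <- u + dt * pop$a * (pop$b * v - u)
  if (!all(is.finite(v)) || !all(is.finite(u)))
    stop(sprintf("non-finite network state at t = %g ms", state$t))
  fired <- v >= 30
  v[fired] <- pop$c[fired]
  u[fired] <- u[fired] + pop$d[fired]
  structure(list(v = v, u = u, fired = fired, t = state$t + dt),
            class = "network_state")
}
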