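#' Astrocyte model constants
#'
#' Fixed constants of the lumped astrocyte compartment: cytosolic calcium
#' `c` exchanging with endoplasmic-reticulum calcium `ce` through the
#' nonlinear flux `calcium_exchange()`, a second messenger `Sm`
#' (IP3-like) driven by the presynaptic signal, and a gliotransmitter
#' level `Gm` gated by cytosolic calcium. All state variables are in
#' dimensionless model units; time constants are in seconds.
#'
#' The second-messenger influx coefficient `sm_influx = 0.06` places the
#' stimulated calcium influx (`0.31 + 0.06 Sm`, up to about 0.361) above
#' the Hopf bifurcation of the calcium subsystem (at influx about 0.34)
#' while leaving the unstimulated influx 0.31 below it, so sustained
#' presynaptic drive switches the astrocyte from a quiescent focus into
#' large-amplitude calcium oscillations and back; see the methods
#' vignette for the bifurcation analysis behind this constant.
#'
#' `k_glio` scales the gliotransmitter feedback current
#' `I_astro = k_glio * delta * Gm` (see [astro_current()]). Its default of
#' 1 is a repository calibration: the peak feedback current
#' (about `0.8 * 1 * 6/7 ~ 0.69`) is of the same order as the inhibitory
#' noise drive, and the gain is small enough that gliotransmitter pulses
#' at normal transporter activity (`delta = 0.8`) leave the withdrawal
#' network asynchronous while transporter inactivation (`delta = 1`)
#' synchronizes it -- the sensitivity window the withdrawal/relapse
#' protocols probe. It is a first-class configuration field, not a fixed
#' model constant; see the methods vignette for the calibration.
#'
#' @param k_glio gliotransmitter current gain (default 1).
#' @param drive_threshold half-activation point of the drive
#'   nonlinearity (default 0.45).
#' @return object of class `astro_parameters`.
#' @export
astro_parameters <- function(k_glio = 1, drive_threshold = 0.45) {
  structure(list(
    k_glio = k_glio,
    drive_threshold = drive_threshold,
    tau_c = 0.05,          # s, cytosolic calcium time constant
    er_flux_gain = 2 / 0.04, # scales exchange flux into dc/dt
    c_influx = 0.31,       # baseline calcium influx
    sm_influx = 0.06,      # second-messenger-modulated influx
    tau_ce = 0.04 * 0.05,  # s, ER calcium time constant
    ex_amp = 0.13,         # exchange-flux amplitude
    ex_half = 0.94,        # c^4 half-saturation in the release term
    leak = 0.004,          # ER leak coefficient
    tau_sm = 5,            # s, second-messenger time constant
    drive_gain = 5,        # tanh slope of the drive nonlinearity
    tau_gm = 0.025,        # s, gliotransmitter time constant
    gm_half = 0.5          # calcium half-activation of release
  ), class = "astro_parameters")
}

#' Default astrocyte initial state
#'
#' @param c,ce,sm,gm initial values (defaults 0.1, 1.0, 0, 0).
#' @return object of class `astro_state` with a time field `t` (s).
#' @export
astro_state <- function(c = 0.1, ce = 1.0, sm = 0, gm = 0) {
  structure(list(c = c, ce = ce, sm = sm, gm = gm, t = 0),
            class = "astro_state")
}

#' Calcium exchange flux between cytosol and endoplasmic reticulum
#'
#' `f(c, ce) = 0.13 c^2/(1 + c^2) - (ce^2/(1 + ce^2)) (c^4/(0.94 + c^4))
#' - 0.004 ce`: a pump term filling the ER, calcium-induced calcium
#' release, and a linear ER leak.
#'
#' @param c cytosolic calcium.
#' @param ce ER calcium.
#' @return flux value (positive values fill the ER).
#' @export
calcium_exchange <- function(c, ce) {
  0.13 * c^2 / (1 + c^2) -
    (ce^2 / (1 + ce^2)) * (c^4 / (0.94 + c^4)) -
    0.004 * ce
}

#' Presynaptic drive activation of the second messenger
#'
#' `1 + tanh(5 * (K_exc * |f1| - 0.45))`, a sigmoid in `(0, 2)` of the
#' rectified presynaptic signal amplitude. At the default drive amplitude
#' `K_exc = 5` a unit-magnitude draw saturates the activation.
#'
#' @param k_exc excitatory drive amplitude of the current mode.
#' @param f1 scalar standard-normal presynaptic-signal draw.
#' @param pars `astro_parameters` (supplies slope and threshold).
#' @return activation in `(0, 2)`.
#' @export
astro_drive <- function(k_exc, f1, pars = astro_parameters()) {
  1 + tanh(pars$drive_gain * (k_exc * abs(f1) - pars$drive_threshold))
}

#' Advance the astrocyte state by one Euler step
#'
#' Forward-Euler integration (in seconds) of
#' \deqn{0.05\, dc/dt = -c - 50 f(c, c_e) + 0.31 + 0.06 S_m}
#' \deqn{0.002\, dc_e/dt = f(c, c_e)}
#' \deqn{5\, dS_m/dt = \mathrm{drive}\,(1 - S_m) - S_m/3}
#' \deqn{0.025\, dG_m/dt = (1 + \tanh(10 (c - 0.5)))(1 - G_m) - G_m/3}
#' with `Sm` and `Gm` clamped to `[0, 1]` after the step to guard against
#' Euler overshoot. One astrocyte step is taken per 1-ms network step
#' (`dt_s = 0.001`).
#'
#' @param state an `astro_state`.
#' @param drive drive activation for this step (see [astro_drive()]).
#' @param dt_s Euler step in seconds (default 0.001).
#' @param pars `astro_parameters`.
#' @return updated `astro_state`.
#' @export
step_astrocyte <- function(state, drive, dt_s = 0.001,
                           pars = astro_parameters()) {
  f <- calcium_exchange(state$c, state$ce)
  dc <- (-state$c - pars$er_flux_gain * f +
           pars$c_influx + pars$sm_influx * state$sm) / pars$tau_c
  dce <- f / pars$tau_ce
  dsm <- (drive * (1 - state$sm) - state$sm / 3) / pars$tau_sm
  dgm <- ((1 + tanh(10 * (state$c - pars$gm_half))) * (1 - state$gm) -
            state$gm / 3) / pars$tau_gm
  c_new <- state$c + dt_s * dc
  ce_new <- state$ce + dt_s * dce
  sm_new <- min(1, max(0, state$sm + dt_s * dsm))
  gm_new <- min(1, max(0, state$gm + dt_s * dgm))
  if (!all(is.finite(c(c_new, ce_new, sm_new, gm_new))))
    stop(sprintf("non-finite astrocyte state at t = %g s", state$t))
  structure(list(c = c_new, ce = ce_new, sm = sm_new, gm = gm_new,
                 t = state$t + dt_s),
            class = "astro_state")
}

#' Gliotransmitter feedback current
#'
#' `I_astro = k_glio * delta * Gm`, broadcast by the engine to the target
#' neurons. `delta` is the transporter-activity factor; `k_glio` the
#' release gain (see [astro_parameters()]).
#'
#' @param gm gliotransmitter level.
#' @param delta transporter-activity factor.
#' @param k_glio current gain (default as in [astro_parameters()]).
#' @return scalar current value.
#' @export
astro_current <- function(gm, delta, k_glio = 1) {
  k_glio * delta * gm
}

#' Integrate the astrocyte alone under a prescribed drive
#'
#' Convenience wrapper for studying the glial compartment in isolation:
#' integrates [step_astrocyte()] for `n_steps` steps under a drive signal
#' supplied either as a constant, a vector of per-step values, or a
#' function of time (s).
#'
#' @param drive scalar, vector of length `n_steps`, or `function(t_s)`.
#' @param n_steps number of Euler steps.
#' @param dt_s step size in seconds (default 0.001).
#' @param init initial `astro_state`.
#' @param pars `astro_parameters`.
#' @return data.frame with columns `time_s`, `c`, `ce`, `sm`, `gm`.
#' @export
simulate_astrocyte <- function(drive, n_steps, dt_s = 0.001,
                               init = astro_state(),
                               pars = astro_parameters()) {
  drv <- if (is.function(drive)) {
    drive((seq_len(n_steps) - 1) * dt_s)
  } else if (length(drive) == 1L) {
    rep(drive, n_steps)
  } else drive
  stopifnot(length(drv) == n_steps)
  astro_trace_cpp(c(init$c, init$ce, init$sm, init$gm), drv, dt_s,
                  astro_pars_vec(pars), t0 = init$t)
}

# Constant vector in the fixed order expected by the compiled core.
astro_pars_vec <- function(pars) {
  unname(unlist(pars[c("tau_c", "er_flux_gain", "c_influx", "sm_influx",
                       "tau_ce", "ex_amp", "ex_half", "leak", "tau_sm",
                       "drive_gain", "drive_threshold", "tau_gm",
                       "gm_half")]))
}
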