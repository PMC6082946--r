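test_that("population parameters follow the excitatory/inhibitory rules", {
  pop <- init_population(800, 200, seed = 42)
  expect_length(pop$a, 1000)
  expect_identical(pop$is_excitatory, c(rep(TRUE, 800), rep(FALSE, 200)))
  exc <- pop$is_excitatory
  expect_true(all(pop$a[exc] == 0.02) && all(pop$b[exc] == 0.2))
  expect_equal(pop$c[exc], -65 + 15 * pop$r[exc]^2)
  expect_equal(pop$d[exc], 8 - 6 * pop$r[exc]^2)
  expect_true(all(pop$c[exc] >= -65 & pop$c[exc] <= -50))
  expect_true(all(pop$d[exc] >= 2 & pop$d[exc] <= 8))
  expect_equal(pop$a[!exc], 0.02 + 0.08 * pop$r[!exc])
  expect_equal(pop$b[!exc], 0.25 - 0.05 * pop$r[!exc])
  expect_true(all(pop$c[!exc] == -65) && all(pop$d[!exc] == 2))
  # closed forms at the extremes of the heterogeneity draw
  expect_equal(c(-65 + 15 * 0, 8 - 6 * 0), c(-65, 8))
  expect_equal(c(0.02 + 0.08 * 1, 0.25 - 0.05 * 1), c(0.1, 0.2))
  expect_identical(pop, init_population(800, 200, seed = 42))
  expect_error(init_population(0, 0), "at least one")
})

test_that("connectivity blocks have the right shape, sign and rescaling", {
  sm <- init_connectivity(800, 200, seed = 7)
  expect_equal(dim(sm$g1), c(1000, 800))
  expect_equal(dim(sm$g2), c(1000, 200))
  expect_equal(dim(sm$S), c(1000, 1000))
  expect_true(all(sm$S[, 1:800] >= 0))
  expect_true(all(sm$S[, 801:1000] <= 0))
  expect_true(all(sm$g1 >= 0 & sm$g1 <= 1))
  # rescaling reuses the same realization, exactly linearly
  sm2 <- rescale_weights(sm, s_inh = -1.4)
  expect_identical(sm2$g1, sm$g1)
  expect_equal(sm2$S[, 801:1000], 1.4 * sm$S[, 801:1000])
  expect_equal(sm2$S[, 1:800], sm$S[, 1:800])
  sm0 <- rescale_weights(sm, s_exc = 0)
  expect_true(all(sm0$S[, 1:800] == 0))
})

test_that("synaptic current sums weight columns of fired sources", {
  S <- matrix(c(0, 0.2, 0.1, 0.5, 0, 0.4, -1, -0.3, 0), nrow = 3)
  expect_equal(synaptic_current(S, c(FALSE, FALSE, FALSE)), c(0, 0, 0))
  expect_equal(synaptic_current(S, c(FALSE, TRUE, FALSE)), S[, 2])
  expect_equal(synaptic_current(S, c(TRUE, FALSE, TRUE)), c(-1, -0.1, 0.1))
  expect_error(synaptic_current(S, c(TRUE, FALSE)), "one flag per source")
  # linearity in the weight scales for a fixed firing pattern
  sm <- init_connectivity(40, 10, seed = 1, s_exc = 0.5, s_inh = -1)
  fired <- rep(c(TRUE, FALSE), 25)
  i1 <- synaptic_current(sm, fired)
  sm2 <- rescale_weights(sm, s_exc = 1.5, s_inh = -2)
  i2 <- synaptic_current(sm2, fired)
  i_exc <- synaptic_current(rescale_weights(sm, s_inh = 0), fired)
  i_inh <- i1 - i_exc
  expect_equal(i2, 3 * i_exc + 2 * i_inh)
})

test_that("external drive scales with mode amplitudes and delta", {
  normal <- mode_parameters("normal")
  expect_equal(external_current(normal, rep(1, 2), rep(1, 2)),
               c(4, 4, 1.6, 1.6))
  acute <- mode_parameters("acute")
  expect_equal(external_current(acute, 1, numeric(0)) /
                 external_current(normal, 1, numeric(0)), 1.5)
  off <- mode_override(normal, delta = 0)
  expect_equal(external_current(off, rnorm(3), rnorm(2)), rep(0, 5))
})

test_that("threshold crossing resets v to c and increments u by d", {
  pop <- rs_population()
  st <- structure(list(v = 31, u = 0, fired = FALSE, t = 0),
                  class = "network_state")
  st2 <- step_neurons(st, pop, I_total = 0)
  expect_true(st2$fired)
  expect_equal(st2$v, -65)
  expect_gt(st2$u, 8 - 1e-9)  # jump by d = 8 from the updated u
})

test_that("an isolated resting neuron stays subthreshold without input", {
  pop <- rs_population()
  st <- structure(list(v = -65, u = 0.2 * -65, fired = FALSE, t = 0),
                  class = "network_state")
  for (i in 1:1000) {
    st <- step_neurons(st, pop, I_total = 0)
    expect_false(st$fired)
  }
  expect_lt(st$v, 30)
})

test_that("tonically driven neuron matches a fine-step integration oracle", {
  # independent forward-Euler oracle at dt = 0.01 ms
  oracle_isi <- local({
    v <- -65; u <- 0.2 * v; dt <- 0.01; spikes <- c()
    for (i in seq_len(150000)) {
      v <- v + dt * (0.04 * v^2 + 5 * v + 140 - u + 10)
      u <- u + dt * 0.02 * (0.2 * v - u)
      if (v >= 30) {
        spikes <- c(spikes, i * dt); v <- -65; u <- u + 8
      }
    }
    median(diff(spikes))
  })
  pop <- rs_population()
  st <- structure(list(v = -65, u = 0.2 * -65, fired = FALSE, t = 0),
                  class = "network_state")
  spikes <- c()
  for (i in 1:1500) {
    st <- step_neurons(st, pop, I_total = 10)
    if (st$fired) spikes <- c(spikes, i)
  }
  expect_gt(length(spikes), 5)
  isi <- median(diff(spikes))
  # the 1-ms production step carries a known discretization bias on the
  # stiff spike upstroke; the same scheme at dt = 0.1 ms converges
  expect_lt(abs(isi - oracle_isi) / oracle_isi, 0.20)
  st <- structure(list(v = -65, u = 0.2 * -65, fired = FALSE, t = 0),
                  class = "network_state")
  spikes_fine <- c()
  for (i in 1:15000) {
    st <- step_neurons(st, pop, I_total = 10, dt = 0.1)
    if (any(st$fired)) spikes_fine <- c(spikes_fine, i * 0.1)
  }
  expect_lt(abs(median(diff(spikes_fine)) - oracle_isi) / oracle_isi,
            0.02)
})

test_that("reference R stepper and compiled engine agree step by step", {
  pop <- init_population(8, 2, seed = 3)
  sm <- init_connectivity(8, 2, seed = 4)
  n_steps <- 200L
  noise <- with_seed(5, matrix(rnorm(10 * n_steps), nrow = 10))
  mode <- mode_parameters("normal")
  # compiled path, gliotransmitter gain zeroed to isolate the neurons
  out <- gliosim:::sim_segment_cpp(
    rep(-65, 10), pop$b * -65, pop$a, pop$b, pop$c,
    pop$d, sm$S, noise, rep(0, n_steps),
    rep(FALSE, 10), c(0.1, 1, 0, 0), 8L,
    mode$k_exc, mode$k_inh, mode$delta, 0, 1, 0.001,
    0L, gliosim:::astro_pars_vec(astro_parameters()), FALSE, FALSE, FALSE)
  # reference path
  st <- structure(list(v = rep(-65, 10), u = pop$b * -65,
                       fired = rep(FALSE, 10), t = 0),
                  class = "network_state")
  spikes <- list()
  for (t in seq_len(n_steps)) {
    I <- synaptic_current(sm, st$fired) +
      external_current(mode, noise[1:8, t], noise[9:10, t])
    st <- step_neurons(st, pop, I)
    spikes[[t]] <- which(st$fired) - 1L
  }
  ref_t <- rep(seq_len(n_steps) - 1L, vapply(spikes, length, integer(1)))
  expect_identical(out$spike_time_ms, as.integer(ref_t))
  expect_identical(out$spike_id, as.integer(unlist(spikes)))
  expect_equal(out$v, st$v)
  expect_equal(out$u, st$u)
})
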