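---
title: "Model and methods: a spiking neuron-astrocyte network for opioid addiction modes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: a spiking neuron-astrocyte network for opioid addiction modes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`gliosim` simulates a post-synaptic cortical circuit of 1000 Izhikevich
neurons — 800 excitatory (regular-spiking family) and 200 inhibitory
(fast-spiking family) — that is driven by a noisy pre-synaptic signal and
monitored by a single lumped astrocyte. Each neuron obeys

$$v' = 0.04 v^2 + 5v + 140 - u + I, \qquad u' = a(bv - u),$$

with the discontinuous reset $v \leftarrow c_i$, $u \leftarrow u + d_i$
whenever $v \ge 30$ mV. Heterogeneity follows the standard cortical
recipe: for excitatory neurons $(a, b) = (0.02, 0.2)$,
$(c_i, d_i) = (-65, 8) + (15, -6)\,r_i^2$; for inhibitory neurons
$(a_i, b_i) = (0.02, 0.25) + (0.08, -0.05)\,r_i$, $(c_i, d_i) = (-65, 2)$,
with $r_i \sim U[0, 1]$. Connectivity is dense and random:
$S = [\,s_{Exc}\,g_1,\; s_{Inh}\,g_2\,]$ with $g_1$ ($1000 \times 800$)
and $g_2$ ($1000 \times 200$) i.i.d. uniform on $[0, 1]$, and
$s_{Exc} = 0.5$, $s_{Inh} = -1$ in the normal state. A spike deposits its
full signed weight on every target for one step (current-based,
delay-free synapses); self-connections are not excluded — at this density
the diagonal is negligible, and it keeps "randomly connected" literal.

The external drive is mode-dependent white noise: each excitatory neuron
receives $\delta K_{Exc} f_{1,i}$ and each inhibitory neuron
$\delta K_{Inh} f_{2,i}$ per 1-ms step, with $f \sim N(0,1)$ and
$\delta$ the astrocytic transporter-activity factor
($0.5$ = enhanced clearance, $0.8$ = normal, $1$ = transporters
inactive). The gliotransmitter feedback current
$I_{Astro} = K_{Glio}\,\delta\,G_m$ is added uniformly to all neurons
(configurable to excitatory targets only).

The astrocyte is a four-variable relaxation system in seconds — cytosolic
calcium $c$, ER calcium $c_e$, second messenger $S_m$ (IP$_3$-like) and
gliotransmitter $G_m$:

$$0.05\,\dot c = -c - 50 f(c, c_e) + (0.31 + 0.06\,S_m)$$
$$0.002\,\dot c_e = f(c, c_e)$$
$$f(c, c_e) = 0.13\frac{c^2}{1+c^2}
  - \frac{c_e^2}{1+c_e^2}\cdot\frac{c^4}{0.94+c^4} - 0.004\,c_e$$
$$5\,\dot S_m = \big(1 + \tanh[5(K_{Exc}|f_1| - 0.45)]\big)(1 - S_m) - S_m/3$$
$$0.025\,\dot G_m = \big(1 + \tanh[10(c - 0.5)]\big)(1 - G_m) - G_m/3$$

Sustained pre-synaptic activity saturates the drive nonlinearity, pushes
$S_m$ to its fixed point $6/7$, and tips the calcium subsystem across a
Hopf bifurcation into slow large-amplitude oscillations (period of order
1 s); each calcium excursion above $0.5$ triggers a fast $G_m$ pulse
toward $6/7$ and hence a pulse of feedback current.

### Two numerical readings the source equations leave open

Two constants in this model family are typographically ambiguous, and the
package documents its readings explicitly:

* **Decay denominators.** The $S_m$ and $G_m$ decay terms are read as
  $-S_m/3$ and $-G_m/3$ (relaxation with divisor 3), the form used
  throughout this glial model family. A cubic reading ($-G_m^3$) changes
  the fixed points but not the qualitative switching; the division
  reading reproduces the $6/7$ saturation used in the tests.
* **Second-messenger influx coefficient.** The package uses
  $0.31 + 0.06\,S_m$ for the calcium influx. Numerical continuation of
  the $(c, c_e)$ subsystem places its Hopf bifurcation at influx
  $\approx 0.34$: a coefficient of $0.006$ would cap the stimulated
  influx at $0.3151$, below the bifurcation for every $S_m \in [0,1]$,
  making stimulation-induced calcium oscillations impossible — yet those
  oscillations are the astrocyte's entire functional role. With $0.06$
  the unstimulated influx ($0.31$) is quiescent and the stimulated
  influx ($\approx 0.361$) oscillates, which is exactly the documented
  on/off behaviour. The constant lives in `astro_parameters()` and can
  be set back by the user.

## Integration scheme

The network uses forward Euler with a 1-ms outer step; the voltage
equation advances in two 0.5-ms half-steps per outer step (input held
constant), $u$ advances once, and the threshold test runs once per outer
step — the reference convention for this neuron family, kept for
reproducibility of its published firing regimes. This scheme carries a
known discretization bias on the stiff spike upstroke: a tonically driven
regular-spiking neuron at $I = 10$ fires with a 52-ms inter-spike
interval at the production step versus 44.8 ms in the $dt \to 0$ limit
(~16%); the same scheme at $dt = 0.1$ ms is within 2% of the limit. The
unit tests pin both facts. Population-level synchronization phenomena,
which are the package's subject, are governed by burst timing rather than
single-spike timing and are stable under step refinement.

The astrocyte advances by one forward-Euler step of $dt_s = 0.001$ s per
network step, i.e. glial time runs in seconds alongside network
milliseconds. This is a deliberate two-timescale convention: the stated
glial time constants (5, 0.05, 0.025 s) only produce the slow calcium
rhythms on a seconds scale, matching the multi-second protocol windows.
$S_m$ and $G_m$ are clamped to $[0, 1]$ after each step to guard against
Euler overshoot; halving $dt_s$ moves the first release time by under 5%
(tested).

## Randomness and reproducibility

A master seed spawns four named streams (heterogeneity, connectivity,
neuron noise, astrocyte drive) via `derive_stream_seeds()`. All noise for
a run is drawn up front per stream, so:

* identical configuration ⇒ bit-identical rasters (tested);
* editing one segment of a protocol never perturbs activity recorded
  before that segment (tested);
* weight interventions rescale the stored $g_1$, $g_2$ — the same
  connectivity realization — so within-run weight comparisons are exact.

The noise is per-neuron i.i.d. per step by default. The alternative
reading — one shared draw for all excitatory and one for all inhibitory
neurons (`noise_shared = TRUE`) — was evaluated and rejected as the
default: common input locks every mode into full-population
synchrony ($\chi \approx 1$ even in the normal and withdrawal states),
contradicting the irregular normal/withdrawal rasters the protocol suite
is built around.

## Protocol schedules

Modes are small parameter records
$(K_{Exc}, K_{Inh}, s_{Exc}, s_{Inh}, \delta$, release scale$)$:

| mode | $K_{Exc}$ | $K_{Inh}$ | $s_{Exc}$ | $s_{Inh}$ | $\delta$ |
|---|---|---|---|---|---|
| normal | 5 | 2 | 0.5 | −1 | 0.8 |
| acute | 7.5 | 1 | 0.5 | −1 | 0.8 |
| chronic | 6.25 | 1.5 | 0.625 | −0.75 | 0.8 |
| withdrawal | 3.75 | 2.5 | 0.56 | −0.875 | 0.8 |

Schedules are contiguous half-open segments mapping time to a mode.
`figure2_schedule()` is the canonical four-mode timeline (normal 0–2 s,
acute 2–3 s, chronic 3–6 s, withdrawal 6–8 s); `figure3_schedule(mode)`
toggles gliotransmitter release off/on at 1 s; `figure4_schedule()`
applies one chronic-mode intervention per second ($K_{Exc} = 3.8$,
$K_{Inh} = 4$, $s_{Exc} = 0.47$, $s_{Inh} = -1.4$, $\delta = 0.5$);
`figure5_schedule()` runs withdrawal, then transporter inactivation
($\delta = 1$), then additionally reduced release.

Design notes:

* **Chronic inputs are piecewise-constant** at the printed values. The
  narrative alternative — ramping the drives from the acute values toward
  normal across the chronic window — is available via an explicit
  segment list, but the printed values are the only quantitative anchor,
  and measured burst statistics are insensitive to the drive level
  across the plausible ramp range ($K_{Exc}$ 4.5–7).
* **Withdrawal in the four-mode timeline keeps $\delta = 0.8$**;
  transporter collapse ($\delta = 1$) is specifically the
  relapse manipulation of the withdrawal–relapse timeline.
* **The release reduction in `figure5_schedule()` defaults to 0.25** (a
  75% cut). No canonical magnitude exists; the value is exposed as an
  argument and `sweep_parameter()` can locate the desynchronization
  threshold.
* Release gating multiplies the current gain ($K_{Glio}$), not $G_m$:
  the astrocyte's internal dynamics continue during "no release" phases,
  so toggling release probes the feedback pathway alone.

## Calibrated constants

**Gliotransmitter gain $K_{Glio} = 1$** (the one constant of the coupled
model with no printed value). Calibration targets the transporter
sensitivity the withdrawal protocols probe: on a warmed-up withdrawal
network, $\chi \approx 0.59$ at $\delta = 0.8$ versus $\chi \approx 1.0$
at $\delta = 1$ for $K_{Glio} = 1$, i.e. normal transporter activity
keeps the state asynchronous while transporter inactivation triggers
relapse-like resynchronization. At $K_{Glio} \ge 1.5$ the $\delta = 0.8$
pulses already synchronize withdrawal (window lost); at $K_{Glio} = 1$
the peak feedback current ($0.8 \cdot 1 \cdot 6/7 \approx 0.69$) also
stays the same order as the inhibitory noise drive. `k_glio` is a
first-class configuration field.

**Synchronization criterion $\chi_{crit} = 0.94$.** The synchrony index
$\chi$ (below) grades continuously from $\approx 0.89$ in the normal
state to $\approx 1.0$ in chronic; the criterion is fixed by rule as the
midpoint of those two medians (10 seeds, four-mode timeline):
"synchronized" means closer to the pathological chronic regime than to
the normal baseline rhythm. One criterion is used everywhere a binary
synchronized/asynchronous call is needed (intervention thresholds,
relapse detection). Note the trade-off: a criterion this high detects the
*first loss of full synchrony* along an intervention sweep; the printed
intervention thresholds correspond to *complete disappearance*, which on
a smooth $\chi$ curve occurs somewhat deeper into the sweep.

## Analysis layer

* **PSC**: population spike count per 1-ms bin; rebinning sums exactly.
* **Spectrogram**: 0.5-s Hamming windows, 90% overlap, per-window mean
  removal (so the mean-rate/DC peak cannot mask rhythms), one-sided
  $|FFT|^2$ scaled so that with a rectangular window per-window power
  sums to the windowed variance (Parseval; tested to $10^{-6}$, and
  bin-by-bin against a direct-DFT oracle to $10^{-9}$). Defaults resolve
  5–10 Hz structure inside 1-s protocol segments; the 2-Hz bin width is
  part of every reported dominant frequency.
* **Dominant frequency**: argmax of the time-averaged spectrum in
  [1, 100] Hz (sub-1-Hz excluded to drop the mean-rate peak), ties
  toward the lower frequency.
* **Synchrony index**: PSC smoothed by a 5-ms boxcar to a rate $r(t)$;
  with $V = \mathrm{Var}_t(r)$ and the independent-firing floor
  $V_0 = \overline{\mathrm{psc}}\cdot\sum h^2$,
  $\chi = \sqrt{\max(0, V - V_0)/(V + V_0)}$. Independent Poisson
  firing gives $\chi \approx 0$; perfectly coincident population spikes
  give $\chi \to 1$. $\chi$ depends on the PSC only (relabeling
  invariant) and is held stable across versions.
* **Synchronized-neuron fraction**: a neuron counts as phase-locked when
  the Pearson correlation between its 10-ms-binned train and the
  leave-one-out population count exceeds 0.3; silent neurons count
  against. This is one defensible operationalization of "synchronized
  neurons"; in regimes with a global collective rhythm the per-neuron
  correlation distribution is unimodal, so the fraction is sensitive to
  the threshold and should be read with its definition attached.

## What the synthetic rasters emulate

`poisson_raster()` and `rhythmic_raster()` generate ground-truth spike
rasters — independent Poisson, sinusoidally rate-modulated (exact
thinning, so the construction is bin-size independent), and optionally a
perfectly coincident subpopulation — so every analysis statistic is
validated against signals with known rate, frequency and coincidence
structure, independently of the simulator. They emulate only
first-order rate/coincidence structure: no refractoriness, no
burst-within-burst structure, no cell-class asymmetry. Passing analysis
tests on them certifies the measurement layer, not the realism of the
simulated biology.

## Simulation sizes used by the test and acceptance suites

All statistical checks run the full 1000-neuron network: ten 8-s
four-mode runs, ten 2-s acute runs, 1-s runs per sweep value
(29 excitatory-drive values and 33 weight values × 5 seeds; 22
inhibitory-weight values × 10 seeds), and 60-s single-astrocyte
integrations. These sizes reproduce the protocol windows at full scale
while keeping a complete suite run in a few minutes on one CPU.

## Known limitations

* The chronic regime of this implementation bursts at 4.6 Hz
  (inter-burst interval ≈ 217 ms, stable across seeds, gains and drive
  levels), which the 2-Hz-resolution spectrogram reports as a 4-Hz
  dominant bin — sitting at, not inside, the lower edge of the 5–10 Hz
  theta band that chronic synchronization is classically assigned to.
* The acute state here is a near-global ~30-Hz collective rhythm; a
  small (~5%) phase-locked subpopulation does not emerge under the
  documented phase-locking rule, and no threshold-free subpopulation
  structure exists in the correlation distribution.
* Chronic-mode synchrony is robust to excitatory-weight attenuation far
  below the normal scale (collapse near $s_{Exc} \approx 0.375$); the
  model does not reproduce high sensitivity of synchronization to small
  weight reductions.
* Current-based delay-free synapses, a single astrocyte, no plasticity:
  weight changes are protocol-imposed, not activity-dependent.
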