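Package: gliosim
Title: Spiking Neuron-Astrocyte Network Simulator for Opioid Addiction Modes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates a 1000-neuron Izhikevich spiking network (800
    excitatory, 200 inhibitory) coupled to a lumped astrocyte whose
    calcium-gated gliotransmitter release feeds a depolarizing current back
    into the network. Declarative protocol schedules encode normal, acute,
    chronic and withdrawal opioid-exposure modes and the intervention
    experiments that manipulate drive amplitudes, synaptic weight scales and
    astrocytic transporter activity. An analysis layer quantifies
    population-spike-count spectrograms, dominant frequencies, theta-band
    power, a population synchrony index and the fraction of neurons
    phase-locked to the population rate, together with synthetic raster
    generators for validating the analysis independently of the simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
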