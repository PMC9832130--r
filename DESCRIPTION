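Package: dendsim
Title: Reduced Compartmental Spiking Neuron Models with Event-Driven
    Dendritic Spikes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Build and simulate reduced compartmental spiking neuron models:
    a soma governed by a leaky integrate-and-fire mechanism with
    conductance-based adaptation and a two-stage voltage reset, passive
    cylindrical dendritic compartments coupled by axial (cable)
    conductances, and a phenomenological event-driven mechanism for
    dendritic sodium spikes with delayed-rectifier potassium
    repolarization.  Conductance-based AMPA, NMDA (with magnesium block)
    and GABA synapses are provided in closed-form and ODE kinetics.
    Includes standard electrophysiology protocols (input resistance,
    membrane time constant, sag, F-I curves, rheobase searches,
    attenuation profiles, expected-versus-actual input-output curves,
    backpropagation classification, passive calibration), neuron-pool
    experiments for coincidence detection of segregated input pathways in
    CA1-like pyramidal cells, and a JSON model document format.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
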