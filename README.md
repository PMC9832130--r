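# dendsim

Reduced compartmental spiking neuron models with event-driven dendritic
spikes, for R.

Point integrate-and-fire (I&F) neurons ignore dendrites; morphologically
detailed models are too costly for networks. `dendsim` implements the
middle ground for computational neuroscientists who want dendritic
computation inside network-scale simulations: neurons built from a few
cylindrical compartments — an adaptive I&F soma plus dendritic segments
standing for functionally distinct regions of the tree — with dendritic
sodium spikes modelled as threshold-triggered events instead of
Hodgkin–Huxley gating.

## The model

Soma (leaky I&F with conductance-based adaptation and a two-stage reset
emulating the action-potential shape):

$$C_m \dot V = -g_L (V-E_L) - g_A (V-E_A) + \textstyle\sum_i I_a^i
  + \sum_j I_{syn}^j + I_{ext}, \qquad
  \tau_A \dot g_A = \bar g_A |V-V_A| - g_A$$

with, on threshold crossing, $V \leftarrow V_{spike}$,
$g_A \leftarrow g_A + b$, and $V \leftarrow V_{reset}$ after 0.5 ms.
Dendrites obey the same passive equation plus phenomenological spike
currents $I_{Na} = -g_{Na}(V-E_{Na})$, $I_{Kdr} = -g_{Kdr}(V-E_K)$ whose
conductances decay exponentially and are stepped up by threshold-gated
events: a sodium event when the local voltage crosses $V_{th}^d$ outside
the refractory period, a delayed-rectifier event a fixed offset later.
Compartments couple through axial conductances from cylinder geometry
(half-cylinder rule by default), synapses are conductance-based
AMPA/NMDA/GABA with dual-exponential kinetics and the sigmoidal NMDA
magnesium block $\sigma(V) = 1/(1 + ([\mathrm{Mg}^{2+}]_o/\beta)\,
e^{-\alpha(V-\gamma)})$.

On top of the simulation engine the package provides the standard
electrophysiology protocols (input resistance, membrane time constant,
sag, F–I curves, dendritic-spike rheobase, attenuation profiles,
expected-vs-actual input–output curves, backpropagation classification,
passive calibration), three calibrated reference models, and the CA1
coincidence-detection pool experiment in which entorhinal-like input to
the distal tuft and CA3-like input to proximal branches activate neurons
only when coincident, with dendritic spikes carrying the activation.

## A worked example

```r
library(dendsim)

model <- model_ca1_9c()          # reduced CA1 pyramidal cell, 9 compartments
passive_properties(model)
#> R_input = 137.11 MOhm, tau_m = 38.29 ms, sag ratio = 1.000, baseline = -70.00 mV

pool <- build_pool(model, 1000)
pw <- ca1_pathways()
rates <- tune_rates(pool, pw, seed = 1)   # conditional-activation tuning
pw$EC_rate <- rates$EC_rate               # 30 Hz
pw$CA3_rate <- rates$CA3_rate             # 34 Hz

run_coincidence(pool, pw, "EC+CA3", seed = 2, dspikes = TRUE)
#> Coincidence run [EC+CA3, dSpikes ON]: n = 1000, 500 ms
#>   active fraction = 77.6%, MFR = 3.292 Hz, distal dSpike P = 100.0%
run_coincidence(pool, pw, "EC+CA3", seed = 3, dspikes = FALSE)
#> Coincidence run [EC+CA3, dSpikes OFF]: n = 1000, 500 ms
#>   active fraction = 10.1%, MFR = 0.202 Hz, distal dSpike P = 0.0%
```

With both pathways active, about three quarters of the pool fires;
removing dendritic spikes silences all but ~10 % of the neurons, each of
which fires exactly one spike — somatic output is conditional on
dendritic spiking, not on raw synaptic depolarization. EC input alone
triggers distal dendritic spikes in most neurons but no somatic output;
CA3 input alone triggers nothing.

A thin command-line front end over the same functions lives at
`inst/cli/dendsim.R` (subcommands `fixtures`, `passive`, `fi`,
`rheobase`, `simulate`, `coincidence`); model documents are plain JSON,
results are CSV/JSON.

## Package layout

* `R/model_core.R` — geometry, passive properties, coupling, model assembly
* `R/dynamics.R` — membrane right-hand sides, axial currents
* `R/synapses.R` — synaptic kinetics, normalization, magnesium block
* `R/engine.R` — stimuli, event-driven fixed-step simulation loop
* `R/protocols.R` — electrophysiology protocols and calibration
* `R/network.R` — pools, pathway tuning, coincidence experiment, grids
* `R/fixtures.R` — the three calibrated reference models
* `R/io.R` — JSON model documents, CSV/JSON result writers
* `vignettes/reduced-compartmental-models.Rmd` — the methods vignette
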