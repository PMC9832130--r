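# Small models reused across tests; all built in code.

# single passive compartment: Cm = 100 pF, gL = 5 nS, tau_m = 20 ms
one_comp <- function(V_th = 1e3) {
  # geometry chosen so the absolute values are round: A = 1e-5 cm^2,
  # hence Cm = 100 pF, gL = 5 nS, tau_m = 20 ms, R_input = 200 MOhm
  cc <- compartment("soma", "soma", length_um = 1e2 / pi, diam_um = 10,
                    cm_uF_cm2 = 10, rm_kOhm_cm2 = 2, spine_factor = 1)
  neuron_model(list(cc),
               soma = soma_params(V_th = V_th, V_spike = V_th + 1,
                                  V_reset = V_th - 10))
}

# soma + one dendrite, passive
two_comp <- function() {
  comps <- list(
    compartment("soma", "soma", 20, 20, spine_factor = 1),
    compartment("dend", "dendrite", 200, 2, spine_factor = 1))
  neuron_model(comps, list(c("soma", "dend")),
               soma = soma_params(V_th = 1e3, V_spike = 1e3 + 1,
                                  V_reset = 990))
}

# soma + chain of three passive dendrites (attenuation tests)
chain_model <- function() {
  comps <- list(
    compartment("soma", "soma", 20, 20, spine_factor = 1),
    compartment("d1", "dendrite", 100, 2, spine_factor = 1),
    compartment("d2", "dendrite", 100, 1.5, spine_factor = 1),
    compartment("d3", "dendrite", 100, 1, spine_factor = 1))
  neuron_model(comps, list(c("soma", "d1"), c("d1", "d2"), c("d2", "d3")),
               soma = soma_params(V_th = 1e3, V_spike = 1e3 + 1,
                                  V_reset = 990))
}

# one dendrite with a dendritic-spike mechanism attached to a quiet soma
dspike_model <- function(enabled = TRUE, with_params = TRUE,
                         t_ref = 5, t_offset = 1.2) {
  dp <- if (with_params)
    dspike_params(gbar_Na = 10, gbar_Kdr = 6, V_th_d = -40,
                  t_ref_Na = t_ref, t_offset_Kdr = t_offset,
                  enabled = enabled)
  comps <- list(
    compartment("soma", "soma", 20, 20, spine_factor = 1),
    compartment("dend", "dendrite", 100, 1.5, spine_factor = 1,
                dspike = dp))
  neuron_model(comps, list(c("soma", "dend")),
               soma = soma_params(V_th = 1e3, V_spike = 1e3 + 1,
                                  V_reset = 990))
}

# steady-state voltages of a passive model under constant injected currents
# (independent linear-algebra oracle): (diag(gL) + L) V = gL*EL + I
passive_steady_state <- function(model, I_pA) {
  L <- diag(model$deg) - model$W
  A <- diag(model$gL, model$n_comp) + L
  solve(A, model$gL * model$EL + I_pA)
}
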