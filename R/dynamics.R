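#' Somatic membrane dynamics (right-hand side)
#'
#' Continuous dynamics of the adaptive leaky integrate-and-fire soma:
#' \deqn{C_m \dot V = -g_L (V - E_L) - g_A (V - E_A) + I_{axial} + I_{syn}
#'       + I_{ext},}
#' \deqn{\tau_A \dot g_A = \bar g_A |V - V_A| - g_A.}
#' All currents in pA, conductances in nS, voltages in mV, time in ms.
#'
#' @param V somatic voltage (mV).
#' @param g_A adaptation conductance (nS).
#' @param params list with \code{Cm}, \code{gL}, \code{EL} plus the fields of
#'   [soma_params()] (\code{V_A} resolved to a number).
#' @param I_axial,I_syn,I_ext input currents (pA).
#' @return Named vector \code{c(dV =, dgA =)} in mV/ms and nS/ms.
#' @export
soma_rhs <- function(V, g_A, params, I_axial = 0, I_syn = 0, I_ext = 0) {
  dV <- (-params$gL * (V - params$EL) - g_A * (V - params$E_A) +
           I_axial + I_syn + I_ext) / params$Cm
  dgA <- (params$gbar_A * abs(V - params$V_A) - g_A) / params$tau_A
  c(dV = dV, dgA = dgA)
}

#' Dendritic membrane dynamics (right-hand side)
#'
#' A dendritic compartment follows the same leaky dynamics as the soma but
#' without adaptation, plus the phenomenological dendritic-spike currents
#' \eqn{I_{Na} = -g_{Na}(V - E_{Na})} and \eqn{I_{Kdr} = -g_{Kdr}(V - E_K)}.
#' Between threshold events the conductances decay exponentially
#' (\eqn{\dot g = -g/\tau}); under voltage clamp this makes the currents
#' themselves decay exponentially with the same time constants.
#'
#' @param V dendritic voltage (mV).
#' @param g_Na,g_Kdr instantaneous spike conductances (nS).
#' @param params list with \code{Cm}, \code{gL}, \code{EL} and the fields of
#'   [dspike_params()].
#' @param I_axial,I_syn,I_ext input currents (pA).
#' @return Named vector \code{c(dV =, dgNa =, dgKdr =)}.
#' @export
dendrite_rhs <- function(V, g_Na = 0, g_Kdr = 0, params,
                         I_axial = 0, I_syn = 0, I_ext = 0) {
  I_Na <- -g_Na * (V - params$E_Na)
  I_Kdr <- -g_Kdr * (V - params$E_K)
  dV <- (-params$gL * (V - params$EL) + I_axial + I_syn +
           I_Na + I_Kdr + I_ext) / params$Cm
  c(dV = dV,
    dgNa = -g_Na / params$tau_Na,
    dgKdr = -g_Kdr / params$tau_Kdr)
}

#' Axial currents between coupled compartments
#'
#' The axial current into compartment \eqn{k} is the sum over its neighbours
#' of \eqn{g_c^{i,k} (V_i - V_k)}: current flows from the more depolarized
#' compartment towards the less depolarized one, and the pairwise terms are
#' exactly antisymmetric, so the total over all compartments is zero.
#'
#' @param model a [neuron_model()].
#' @param V voltage vector (mV), one entry per compartment, model order.
#' @return Vector of axial currents (pA) into each compartment.
#' @export
axial_currents <- function(model, V) {
  stopifnot(inherits(model, "neuron_model"), length(V) == model$n_comp)
  unname(as.numeric(V %*% model$W) - V * model$deg)
}
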