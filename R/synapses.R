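#' Magnesium-block parameters for NMDA synapses
#'
#' The NMDA conductance is gated by a sigmoidal voltage dependence caused by
#' extracellular magnesium,
#' \deqn{\sigma(V) = \frac{1}{1 + \frac{[Mg^{2+}]_o}{\beta}
#'       e^{-\alpha (V - \gamma)}},}
#' with the conventional parameterization \eqn{\alpha = 0.062\,mV^{-1}},
#' \eqn{\beta = 3.57\,mM}, \eqn{\gamma = 0\,mV} and 1 mM external magnesium.
#'
#' @param alpha voltage sensitivity (1/mV).
#' @param beta magnesium affinity constant (mM).
#' @param gamma voltage offset (mV).
#' @param mg_out external magnesium concentration (mM).
#' @return Object of class \code{"mg_params"}.
#' @export
mg_params <- function(alpha = 0.062, beta = 3.57, gamma = 0, mg_out = 1) {
  if (alpha <= 0 || beta <= 0 || mg_out <= 0)
    stop("alpha, beta and mg_out must be strictly positive", call. = FALSE)
  structure(list(alpha = alpha, beta = beta, gamma = gamma, mg_out = mg_out),
            class = "mg_params")
}

#' NMDA magnesium-block voltage dependence
#'
#' @param mg an [mg_params()] object.
#' @param V membrane voltage (mV), vectorized.
#' @return \eqn{\sigma(V) \in (0, 1)}; strictly increasing in V.
#' @examples
#' mg_sigma(mg_params(), 0)   # about 0.781 at 0 mV
#' @export
mg_sigma <- function(mg, V) {
  stopifnot(inherits(mg, "mg_params"))
  1 / (1 + (mg$mg_out / mg$beta) * exp(-mg$alpha * (V - mg$gamma)))
}

#' Declare a synapse slot
#'
#' A synapse slot on a compartment describes one presynaptic source:
#' receptor kind (AMPA, NMDA or GABA), peak conductance, reversal potential,
#' kinetics and, for NMDA, magnesium-block parameters.  Time dependence can
#' be the saturating dual-exponential ODE (default), a single-exponential
#' decay ODE, or the closed-form dual-exponential waveform.
#'
#' Kind-specific defaults: AMPA rise/decay 0.5/3 ms, E = 0 mV; NMDA 2/60 ms,
#' E = 0 mV, with magnesium block; GABA 0.5/8 ms, E = -75 mV.
#'
#' @param kind \code{"AMPA"}, \code{"NMDA"} or \code{"GABA"}.
#' @param gbar peak conductance (nS).
#' @param name unique identifier used to address the slot from stimuli.
#' @param E_syn reversal potential (mV); \code{NULL} picks the kind default.
#' @param tau_rise,tau_decay kinetic time constants (ms); must satisfy
#'   \code{tau_decay > tau_rise} for dual-exponential kinetics.  The equal
#'   time-constant (alpha function) limit is rejected, not special-cased.
#' @param kinetics \code{"dual_exp_ode"}, \code{"single_exp"} or
#'   \code{"closed_form"}.
#' @param mg [mg_params()]; mandatory for NMDA (default-constructed when
#'   omitted) and forbidden otherwise.
#' @return Object of class \code{"synapse_params"}.
#' @export
synapse_params <- function(kind = c("AMPA", "NMDA", "GABA"), gbar, name,
                           E_syn = NULL, tau_rise = NULL, tau_decay = NULL,
                           kinetics = c("dual_exp_ode", "single_exp",
                                        "closed_form"),
                           mg = NULL) {
  kind <- match.arg(kind)
  kinetics <- match.arg(kinetics)
  if (gbar < 0) stop("gbar must be >= 0", call. = FALSE)
  def <- switch(kind,
                AMPA = list(E = 0, tr = 0.5, td = 3),
                NMDA = list(E = 0, tr = 2, td = 60),
                GABA = list(E = -75, tr = 0.5, td = 8))
  if (is.null(E_syn)) E_syn <- def$E
  if (is.null(tau_rise)) tau_rise <- def$tr
  if (is.null(tau_decay)) tau_decay <- def$td
  if (tau_rise <= 0 || tau_decay <= 0)
    stop("time constants must be strictly positive", call. = FALSE)
  if (kinetics != "single_exp" && tau_decay <= tau_rise)
    stop("invalid kinetics: tau_decay must exceed tau_rise ",
         "for dual-exponential synapses", call. = FALSE)
  if (kind == "NMDA") {
    if (is.null(mg)) mg <- mg_params()
    stopifnot(inherits(mg, "mg_params"))
  } else if (!is.null(mg)) {
    stop("magnesium block applies to NMDA synapses only", call. = FALSE)
  }
  structure(list(kind = kind, gbar = gbar, name = name, E_syn = E_syn,
                 tau_rise = tau_rise, tau_decay = tau_decay,
                 kinetics = kinetics, mg = mg),
            class = "synapse_params")
}

#' Peak time and normalization factor of the dual-exponential waveform
#'
#' For the closed-form dual-exponential conductance waveform
#' \eqn{s(t) = e^{-t/\tau_d} - e^{-t/\tau_r}} (time measured from the
#' presynaptic spike) the peak occurs at
#' \deqn{t_{peak} = \frac{\tau_d \tau_r}{\tau_d - \tau_r}
#'       \ln(\tau_d/\tau_r),}
#' and the normalization factor \eqn{f_{syn} = 1/s(t_{peak})} rescales the
#' waveform so that a single presynaptic spike reaches exactly the peak
#' conductance \eqn{\bar g_{syn}}.  Single-exponential kinetics need no
#' normalization (\eqn{f_{syn} = 1}).
#'
#' @param x a [synapse_params()] object, or the rise time constant (ms) when
#'   \code{tau_decay} is also given.
#' @param tau_decay decay time constant (ms), if \code{x} is numeric.
#' @return Named vector with \code{t_peak} (ms) and \code{f_syn}.
#' @examples
#' syn_peak_norm(2, 10)  # t_peak = 4.024 ms, f_syn = 1.869
#' @export
syn_peak_norm <- function(x, tau_decay = NULL) {
  if (inherits(x, "synapse_params")) {
    if (x$kinetics == "single_exp")
      return(c(t_peak = 0, f_syn = 1))
    tr <- x$tau_rise; td <- x$tau_decay
  } else {
    tr <- x; td <- tau_decay
  }
  if (td <= tr || tr <= 0)
    stop("invalid kinetics: require tau_decay > tau_rise > 0", call. = FALSE)
  tp <- td * tr / (td - tr) * log(td / tr)
  s_peak <- exp(-tp / td) - exp(-tp / tr)
  c(t_peak = tp, f_syn = 1 / s_peak)
}

#' Closed-form synaptic conductance waveform
#'
#' Evaluates the (unnormalized) time dependence of the synaptic gating
#' variable for a single presynaptic spike at \code{t_pre}: the dual
#' exponential \eqn{s(t) = H(t - t_{pre}) (e^{-(t-t_{pre})/\tau_d} -
#' e^{-(t-t_{pre})/\tau_r})} or the simple decay
#' \eqn{s(t) = H(t - t_{pre}) e^{-(t-t_{pre})/\tau_d}}, where \eqn{H} is the
#' Heaviside step (1 for non-negative argument).
#'
#' @param params a [synapse_params()].
#' @param t time (ms), vectorized.
#' @param t_pre presynaptic spike time (ms).
#' @param normalized logical; multiply the dual-exponential form by its
#'   normalization factor so the peak is exactly 1.
#' @return Dimensionless gating values.
#' @export
closed_form_waveform <- function(params, t, t_pre = 0, normalized = FALSE) {
  stopifnot(inherits(params, "synapse_params"))
  dt <- t - t_pre
  H <- as.numeric(dt >= 0)
  if (params$kinetics == "single_exp") {
    s <- H * exp(-pmax(dt, 0) / params$tau_decay)
  } else {
    s <- H * (exp(-pmax(dt, 0) / params$tau_decay) -
              exp(-pmax(dt, 0) / params$tau_rise))
    if (normalized)
      s <- s * syn_peak_norm(params)["f_syn"]
  }
  unname(s)
}

#' Advance synapse kinetic state and deliver presynaptic spikes
#'
#' Pure single-synapse reference kinetics, exposed for testing and for
#' closed-form work outside the simulation engine (the engine integrates the
#' same equations vectorized).  Dual-exponential ODE:
#' \deqn{\dot s = -s/\tau_d + x (1 - s)/\tau_r, \qquad \dot x = -x/\tau_r,}
#' with \eqn{x \leftarrow x + 1} on each presynaptic spike; the \eqn{(1-s)}
#' term saturates \eqn{s} in [0, 1].  Single-exponential:
#' \eqn{\dot s = -s/\tau_d} with \eqn{s \leftarrow s + 1} on a spike.
#'
#' @param params a [synapse_params()].
#' @param state named vector \code{c(s =, x =)}.
#' @param dt time step (ms) for \code{kinetics_step} (forward Euler).
#' @return Updated state vector.
#' @export
kinetics_step <- function(params, state, dt) {
  s <- state[["s"]]; x <- state[["x"]]
  if (params$kinetics == "single_exp") {
    s <- s + dt * (-s / params$tau_decay)
  } else {
    ds <- -s / params$tau_decay + x * (1 - s) / params$tau_rise
    dx <- -x / params$tau_rise
    s <- s + dt * ds
    x <- x + dt * dx
  }
  c(s = s, x = x)
}

#' @rdname kinetics_step
#' @export
on_presyn_spike <- function(params, state) {
  if (params$kinetics == "single_exp")
    state[["s"]] <- state[["s"]] + 1
  else
    state[["x"]] <- state[["x"]] + 1
  state
}

#' Total synaptic current onto one compartment
#'
#' Sums the currents of a set of synapse slots targeting the same
#' compartment at clamped voltage \code{V}:
#' \deqn{I = -\sum_j \bar g_j f_j s_j (V - E_j) \sigma_j(V),}
#' with \eqn{\sigma(V)} the magnesium block for NMDA slots and 1 otherwise.
#' The sign convention matches the leak term of the membrane equation: the
#' current is depolarizing (positive) when \eqn{V < E_{syn}}.
#'
#' @param synapses list of [synapse_params()] targeting one compartment.
#' @param s numeric vector of gating states, one per synapse.
#' @param V membrane voltage (mV).
#' @return Current in pA.
#' @export
compartment_synaptic_current <- function(synapses, s, V) {
  stopifnot(length(synapses) == length(s))
  total <- 0
  for (j in seq_along(synapses)) {
    sp <- synapses[[j]]
    f <- unname(syn_peak_norm_safe(sp))
    sig <- if (sp$kind == "NMDA") mg_sigma(sp$mg, V) else 1
    total <- total - sp$gbar * f * s[j] * (V - sp$E_syn) * sig
  }
  total
}

# f_syn accessor tolerating single_exp
syn_peak_norm_safe <- function(sp) {
  if (sp$kinetics == "single_exp") 1 else syn_peak_norm(sp)["f_syn"]
}
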