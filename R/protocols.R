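#' Passive membrane properties from a current-step protocol
#'
#' Replicates the standard current-clamp protocol: after a settling period
#' the test current (default -10 pA, 1000 ms, the conventional
#' hyperpolarizing probe) is injected into the soma and the somatic voltage
#' response is analysed.
#'
#' * input resistance: \eqn{R_{input} = |\Delta V_{ss} / I|}, with the
#'   steady-state voltage taken as the mean over the final 10% of the pulse;
#' * membrane time constant: single-exponential fit (log-linear least
#'   squares) to the charging transient, using the samples between 5% and
#'   90% of the approach to steady state;
#' * sag ratio: \eqn{(V_{base} - V_{ss}) / (V_{base} - V_{min})} for a
#'   hyperpolarizing step, so 1 means no sag.  The leak-only membrane has no
#'   sag mechanism; the measurement is provided for models extended with
#'   one, and for protocol parity with experimental reports.
#'
#' @param model a [neuron_model()].
#' @param I_test test current (pA).
#' @param duration pulse duration (ms).
#' @param settle settling time before the pulse (ms).
#' @param dt integration step (ms).
#' @param method integrator.
#' @return List of class \code{"passive_props"}: \code{R_input_MOhm},
#'   \code{tau_m_ms}, \code{sag_ratio}, \code{baseline_mV}.
#' @export
passive_properties <- function(model, I_test = -10, duration = 1000,
                               settle = 200, dt = 0.1, method = "euler") {
  stopifnot(I_test != 0)
  soma <- model$comp_names[model$soma_idx]
  sim <- simulate_model(model,
                        list(stim_step(soma, I_test, onset = settle,
                                       duration = duration)),
                        duration = settle + duration, dt = dt,
                        method = method, log_events = FALSE)
  v <- sim$V[, soma]
  tt <- sim$time
  in_pulse <- tt >= settle & tt <= settle + duration
  V_base <- v[max(which(tt < settle))]
  tail_w <- tt >= settle + 0.9 * duration & in_pulse
  V_ss <- mean(v[tail_w])
  V_ext <- if (I_test < 0) min(v[in_pulse]) else max(v[in_pulse])
  dV <- V_ss - V_base
  R_input <- abs(dV / I_test) * 1e3  # mV/pA -> MOhm

  # charging transient fit on its final 63% (frac in (0.37, 0.95)), where
  # the slowest membrane eigenmode dominates over charge redistribution
  w <- which(in_pulse)
  frac <- (v[w] - V_base) / dV  # 0 at pulse onset -> 1 at steady state
  use <- frac > 0.37 & frac < 0.95
  use <- use & seq_along(use) <= which.max(frac >= 0.95)  # pre-sag segment
  if (sum(use) < 3)
    stop("tau_m fit failure: transient too fast for dt = ", dt, call. = FALSE)
  y <- log(1 - frac[use])
  t_rel <- tt[w][use] - settle
  tau_m <- -1 / stats::coef(stats::lm(y ~ t_rel))[["t_rel"]]

  sag <- if (abs(V_base - V_ext) < 1e-12) 1 else (V_base - V_ss) / (V_base - V_ext)
  structure(list(R_input_MOhm = R_input, tau_m_ms = tau_m,
                 sag_ratio = sag, baseline_mV = V_base),
            class = "passive_props")
}

#' @export
print.passive_props <- function(x, ...) {
  cat(sprintf("R_input = %.2f MOhm, tau_m = %.2f ms, sag ratio = %.3f, baseline = %.2f mV\n",
              x$R_input_MOhm, x$tau_m_ms, x$sag_ratio, x$baseline_mV))
  invisible(x)
}

#' F-I curve
#'
#' Somatic firing rate as a function of injected current amplitude: each
#' amplitude is applied as a long somatic step and the rate is the somatic
#' spike count divided by the pulse duration.
#'
#' @param model a [neuron_model()].
#' @param currents current amplitudes (pA), sorted ascending.
#' @param duration pulse duration (ms).
#' @param settle settling time before the pulse (ms).
#' @param dt integration step (ms).
#' @return \code{data.frame(I_pA, rate_Hz)}.
#' @export
fi_curve <- function(model, currents, duration = 1000, settle = 100,
                     dt = 0.1) {
  stopifnot(!is.unsorted(currents))
  soma <- model$comp_names[model$soma_idx]
  rates <- vapply(currents, function(a) {
    sim <- simulate_model(model,
                          list(stim_step(soma, a, onset = settle,
                                         duration = duration)),
                          duration = settle + duration, dt = dt,
                          record = "none")
    sum(sim$events$event == "soma_spike") / duration * 1e3
  }, numeric(1))
  data.frame(I_pA = currents, rate_Hz = rates)
}

#' Rheobase search by bisection
#'
#' Finds the smallest current amplitude (to the requested resolution) whose
#' square pulse into the given compartment elicits at least one target
#' event: a local dendritic sodium event or a somatic spike.  The default
#' 5 ms pulse is the conventional probe for the dendritic-spike current
#' threshold.
#'
#' @param model a [neuron_model()].
#' @param target compartment receiving the pulse.
#' @param pulse_duration pulse width (ms).
#' @param event \code{"dspike"} (a sodium event in \code{target}) or
#'   \code{"soma_spike"}.
#' @param resolution bracket width at return (pA).
#' @param bounds search interval (pA).
#' @param settle pre-pulse settling time (ms).
#' @param tail post-pulse observation time (ms).
#' @param dt integration step (ms).
#' @return List of class \code{"rheobase"}: \code{rheobase_pA},
#'   \code{compartment}, \code{pulse_duration_ms}, \code{resolution_pA}.
#'   The bracket invariant holds at return: the event fires at
#'   \code{rheobase_pA} but not at the highest tested subthreshold
#'   amplitude.
#' @export
find_rheobase <- function(model, target, pulse_duration = 5,
                          event = c("dspike", "soma_spike"),
                          resolution = 1, bounds = c(0, 2000),
                          settle = 20, tail = 50, dt = 0.1) {
  event <- match.arg(event)
  fires <- function(amp) {
    sim <- simulate_model(model,
                          list(stim_step(target, amp, onset = settle,
                                         duration = pulse_duration)),
                          duration = settle + pulse_duration + tail,
                          dt = dt, record = "none")
    ev <- sim$events
    if (event == "dspike")
      any(ev$event == "dspike_na" & ev$compartment == target)
    else
      any(ev$event == "soma_spike")
  }
  lo <- bounds[1]; hi <- bounds[2]
  if (!fires(hi))
    stop("rheobase search failure: no ", event, " elicited at ", hi, " pA",
         call. = FALSE)
  if (fires(lo))
    stop("rheobase search failure: event already present at lower bound",
         call. = FALSE)
  while (hi - lo > resolution) {
    mid <- (hi + lo) / 2
    if (fires(mid)) hi <- mid else lo <- mid
  }
  structure(list(rheobase_pA = hi, compartment = target,
                 pulse_duration_ms = pulse_duration,
                 resolution_pA = resolution),
            class = "rheobase")
}

#' @export
print.rheobase <- function(x, ...) {
  cat(sprintf("rheobase(%s, %g ms pulse) = %.4g pA (resolution %g pA)\n",
              x$compartment, x$pulse_duration_ms, x$rheobase_pA,
              x$resolution_pA))
  invisible(x)
}

#' Voltage attenuation profiles along the dendritic tree
#'
#' Two complementary measurements of somatodendritic attenuation:
#'
#' * \code{"steady_state_out"}: a long current pulse at the soma; the ratio
#'   of dendritic to somatic steady-state deflection
#'   (\eqn{dV_{dend}/dV_{soma}}) per compartment quantifies outward
#'   (soma-to-dendrite) attenuation.
#' * \code{"epsp_in"}: one synapse slot per location is activated with a
#'   single presynaptic spike; the ratio of the somatic to the local peak
#'   deflection (\eqn{dV_{soma}/dV_{dend}}) quantifies inward attenuation
#'   of synaptic potentials.
#'
#' @param model a [neuron_model()].
#' @param mode measurement direction (see above).
#' @param I_soma somatic pulse (pA) for the steady-state mode.
#' @param duration pulse duration (ms).
#' @param settle settling time (ms).
#' @param dt integration step (ms).
#' @return \code{data.frame(compartment, ratio)}; the ratio at the soma
#'   itself is 1 by construction.
#' @export
attenuation_profiles <- function(model,
                                 mode = c("steady_state_out", "epsp_in"),
                                 I_soma = -10, duration = 1000, settle = 200,
                                 dt = 0.1) {
  mode <- match.arg(mode)
  soma <- model$comp_names[model$soma_idx]
  if (mode == "steady_state_out") {
    sim <- simulate_model(model,
                          list(stim_step(soma, I_soma, onset = settle,
                                         duration = duration)),
                          duration = settle + duration, dt = dt,
                          log_events = FALSE)
    base <- sim$V[max(which(sim$time < settle)), ]
    tail_w <- sim$time >= settle + 0.9 * duration
    ss <- colMeans(sim$V[tail_w, , drop = FALSE])
    dV <- ss - base
    ratio <- dV / dV[soma]
    return(data.frame(compartment = model$comp_names,
                      ratio = unname(ratio[model$comp_names])))
  }
  # epsp_in: first synapse slot per compartment that has one
  rows <- list()
  for (ci in seq_len(model$n_comp)) {
    slots <- model$syn$name[model$syn$target == ci]
    if (!length(slots)) next
    cn <- model$comp_names[ci]
    sim <- simulate_model(model, list(stim_spikes(slots[1], settle)),
                          duration = settle + 100, dt = dt,
                          log_events = FALSE)
    base <- sim$V[max(which(sim$time < settle)), ]
    w <- sim$time >= settle
    pk_d <- max(sim$V[w, cn]) - base[cn]
    pk_s <- max(sim$V[w, soma]) - base[soma]
    rows[[length(rows) + 1L]] <-
      data.frame(compartment = cn,
                 ratio = if (ci == model$soma_idx) 1 else pk_s / pk_d)
  }
  do.call(rbind, rows)
}

#' Expected-versus-actual input-output curve
#'
#' Measures dendritic/somatic integration gain: for each input count
#' \eqn{n}, \eqn{n} independent copies of the named synapse slots are
#' placed on their compartment and activated quasi-simultaneously (one
#' presynaptic spike per copy, staggered by \code{isi}, default 0.1 ms).
#' The peak depolarization at \code{measure_at} is compared with the
#' expected value \eqn{n \times} (unitary peak), i.e. the linear arithmetic
#' sum of unitary responses.  The curve is classified supralinear if any
#' actual/expected ratio exceeds \eqn{1 +} margin, sublinear if all ratios
#' fall below \eqn{1 -} margin, and linear otherwise.
#'
#' @param model a [neuron_model()].
#' @param synapses names of the synapse slots to replicate and co-activate
#'   (e.g. the AMPA and NMDA components on one branch).
#' @param n_range integer vector of input counts.
#' @param isi inter-spike interval across the synapse copies (ms).
#' @param measure_at compartment whose peak response is measured (default:
#'   the soma).
#' @param margin relative deviation from the identity line used for
#'   classification (default 5%).
#' @param settle pre-stimulus settling time (ms).
#' @param window observation window after stimulus onset (ms).
#' @param dt integration step (ms).
#' @return Object of class \code{"io_curve"}: a data frame with
#'   \code{n_synapses}, \code{expected_mV}, \code{actual_mV}, plus a
#'   \code{mode} attribute in \{supralinear, sublinear, linear\}.
#' @export
expected_vs_actual <- function(model, synapses, n_range, isi = 0.1,
                               measure_at = NULL, margin = 0.05,
                               settle = 50, window = 50, dt = 0.1) {
  if (is.null(measure_at)) measure_at <- model$comp_names[model$soma_idx]
  base_syn <- lapply(synapses, function(sn) {
    ci <- model$syn$target[match(sn, model$syn$name)]
    if (is.na(ci)) stop("unknown synapse slot '", sn, "'", call. = FALSE)
    cc <- model$compartments[[ci]]
    sp <- cc$synapses[[which(vapply(cc$synapses, `[[`, character(1),
                                    "name") == sn)]]
    list(comp = ci, params = sp)
  })
  replicated <- function(nsyn) {
    comps <- model$compartments
    stims <- list()
    for (bs in base_syn) {
      extra <- lapply(seq_len(nsyn), function(i) {
        sp <- bs$params
        sp$name <- paste0(sp$name, "_rep", i)
        sp
      })
      old <- comps[[bs$comp]]$synapses
      keep <- vapply(old, function(sp)
        !(sp$name %in% vapply(base_syn, function(b) b$params$name,
                              character(1))), logical(1))
      comps[[bs$comp]]$synapses <- c(old[keep], extra)
      for (i in seq_len(nsyn))
        stims[[length(stims) + 1L]] <-
          stim_spikes(paste0(bs$params$name, "_rep", i),
                      settle + (i - 1) * isi)
    }
    m2 <- neuron_model(unname(comps), model$edges, soma = model$soma,
                       coupling_method = model$coupling_method,
                       coupling_overrides = model$coupling_overrides)
    m2$dspikes_on <- model$dspikes_on
    list(model = m2, stims = stims)
  }
  peak_for <- function(nsyn) {
    rp <- replicated(nsyn)
    sim <- simulate_model(rp$model, rp$stims,
                          duration = settle + nsyn * isi + window, dt = dt,
                          log_events = FALSE)
    base <- sim$V[max(which(sim$time < settle)), measure_at]
    max(sim$V[sim$time >= settle, measure_at]) - base
  }
  unitary <- peak_for(1L)
  actual <- vapply(n_range, peak_for, numeric(1))
  expected <- n_range * unitary
  ratio <- actual / expected
  # n = 1 equals the identity by construction and carries no information
  cl <- ratio[n_range > 1]
  mode <- if (any(cl > 1 + margin)) "supralinear"
          else if (all(cl < 1 - margin)) "sublinear"
          else "linear"
  out <- data.frame(n_synapses = n_range, expected_mV = expected,
                    actual_mV = actual)
  attr(out, "mode") <- mode
  attr(out, "measure_at") <- measure_at
  class(out) <- c("io_curve", "data.frame")
  out
}

#' @export
print.io_curve <- function(x, ...) {
  cat(sprintf("Input-output curve at '%s': %s\n",
              attr(x, "measure_at"), attr(x, "mode")))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Peak of the first temporal derivative of a voltage trace
#'
#' @param sim a single-neuron \code{"simulation"} with recorded voltage.
#' @param compartment compartment name.
#' @param window \code{c(t0, t1)} in ms (default: the whole trace).
#' @return Maximum forward-difference dV/dt (mV/ms) in the window.
#' @export
peak_dvdt <- function(sim, compartment, window = NULL) {
  stopifnot(inherits(sim, "simulation"), sim$n == 1L, !is.null(sim$V))
  tt <- sim$time
  if (is.null(window)) window <- range(tt)
  if (window[1] < tt[1] - .t_tol || window[2] > tt[length(tt)] + .t_tol)
    stop("window outside the recorded trace", call. = FALSE)
  v <- sim$V[, compartment]
  d <- diff(v) / diff(tt)
  tm <- (tt[-1] + tt[-length(tt)]) / 2
  max(d[tm >= window[1] & tm <= window[2]])
}

#' Backpropagation profile of the dendritic tree
#'
#' Injects a long somatic step current and classifies every dendritic
#' compartment by its response to the resulting somatic action potentials:
#' \code{"full_dspike"} if the compartment generated at least one local
#' sodium event (a backpropagating dendritic spike), \code{"spikelet"} if no
#' local event fired but sharp subthreshold deflections (peak dV/dt above
#' \code{spikelet_dvdt}) followed somatic spikes, and \code{"none"}
#' otherwise.
#'
#' @param model a [neuron_model()].
#' @param I_soma somatic step amplitude (pA).
#' @param duration step duration (ms).
#' @param settle pre-stimulus settling time (ms).
#' @param spikelet_dvdt dV/dt criterion for a spikelet (mV/ms).
#' @param dt integration step (ms).
#' @return \code{data.frame(compartment, n_dspikes, class)} over dendritic
#'   compartments.
#' @export
bpap_profile <- function(model, I_soma, duration = 300, settle = 50,
                         spikelet_dvdt = 2, dt = 0.1) {
  soma <- model$comp_names[model$soma_idx]
  sim <- simulate_model(model,
                        list(stim_step(soma, I_soma, onset = settle,
                                       duration = duration)),
                        duration = settle + duration + 50, dt = dt)
  ev <- sim$events
  soma_t <- ev$time[ev$event == "soma_spike"]
  dend <- model$comp_names[-model$soma_idx]
  rows <- lapply(dend, function(cn) {
    nds <- sum(ev$event == "dspike_na" & ev$compartment == cn)
    cls <- if (nds > 0) "full_dspike" else {
      sharp <- FALSE
      for (ts in soma_t) {
        pd <- peak_dvdt(sim, cn, c(ts, min(ts + 5, max(sim$time))))
        if (pd >= spikelet_dvdt) { sharp <- TRUE; break }
      }
      if (sharp) "spikelet" else "none"
    }
    data.frame(compartment = cn, n_dspikes = nds, class = cls,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Calibrate passive parameters to target membrane constants
#'
#' Implements the standard two-stage passive calibration for reduced
#' models: first the specific membrane resistivity of every compartment is
#' set from the target membrane time constant
#' (\eqn{\tau_m = c_m r_m}, preserving each compartment's specific
#' capacitance and spine factor), then all membrane capacitances and leak
#' conductances are jointly scaled by a single factor (bisection) until the
#' measured somatic input resistance is within \code{tol} of the target.
#' The joint scaling leaves \eqn{\tau_m} unchanged by construction.
#'
#' @param model a [neuron_model()].
#' @param tau_m_target target membrane time constant (ms).
#' @param R_input_target target input resistance (MOhm).
#' @param tol relative tolerance on the achieved input resistance.
#' @param scale_bounds admissible joint scale factors.
#' @param dt integration step (ms) for the measurement protocol.
#' @return List: \code{model} (recalibrated), \code{scale} (joint factor),
#'   \code{achieved} (the [passive_properties()] of the result).
#' @export
calibrate_passive <- function(model, tau_m_target, R_input_target,
                              tol = 0.02, scale_bounds = c(0.1, 10),
                              dt = 0.1) {
  stopifnot(tau_m_target > 0, R_input_target > 0)
  rebuild <- function(scale) {
    comps <- lapply(model$compartments, function(cc) {
      cc$rm_kOhm_cm2 <- tau_m_target / cc$cm_uF_cm2 / scale
      cc$cm_uF_cm2 <- cc$cm_uF_cm2 * scale
      cc
    })
    m2 <- neuron_model(unname(comps), model$edges, soma = model$soma,
                       coupling_method = model$coupling_method,
                       coupling_overrides = model$coupling_overrides)
    m2$dspikes_on <- model$dspikes_on
    m2
  }
  rin_at <- function(scale)
    tryCatch(passive_properties(rebuild(scale), dt = dt)$R_input_MOhm,
             # a divergent (too lightly capacitive) candidate behaves like
             # an arbitrarily large input resistance for the bisection
             error = function(e) Inf)
  lo <- scale_bounds[1]; hi <- scale_bounds[2]
  # R_input decreases monotonically with the joint scale
  r_lo <- rin_at(lo); r_hi <- rin_at(hi)
  if (R_input_target > r_lo || R_input_target < r_hi)
    stop("calibration failure: target R_input ", R_input_target,
         " MOhm unattainable within scale bounds [", lo, ", ", hi, "]",
         call. = FALSE)
  for (it in 1:60) {
    mid <- sqrt(lo * hi)
    r <- rin_at(mid)
    if (abs(r - R_input_target) / R_input_target <= tol * 0.5) break
    if (r > R_input_target) lo <- mid else hi <- mid
  }
  out <- rebuild(mid)
  list(model = out, scale = mid, achieved = passive_properties(out, dt = dt))
}
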