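#' Stimulus constructors
#'
#' Stimuli attach either an injected current to a named compartment or a
#' presynaptic spike source to a named synapse slot.
#'
#' * `stim_step()`: square current pulse (pA) into a compartment.
#' * `stim_noise()`: Gaussian noise current; an independent value
#'   `rnorm(mean, sd)` is drawn for every integration step (the standard
#'   deviation is fixed per step, not rescaled with `dt`), independently for
#'   every neuron of a pool.
#' * `stim_spikes()`: explicit presynaptic spike times (ms), shared by all
#'   neurons of a pool.
#' * `stim_train()`: a quasi-synchronous train of `n_spikes` presynaptic
#'   spikes at inter-spike interval `isi` starting at `t0` (see
#'   [synchronous_train()]).
#' * `stim_poisson()`: a homogeneous Poisson spike source; every neuron of a
#'   pool receives an independent realization of the same rate.
#'
#' Stochastic stimuli (`stim_noise`, `stim_poisson`) require a `seed`
#' argument to [simulate_model()]; each stimulus draws from its own stream
#' derived from the master seed and the stimulus position, so adding a
#' stimulus never perturbs the realizations of the others.
#'
#' @param target compartment name (current stimuli).
#' @param synapse synapse slot name (spike stimuli).
#' @param amplitude_pA,mean_pA,sd_pA current parameters (pA).
#' @param onset,duration onset time and duration (ms).
#' @param times numeric spike times (ms).
#' @param n_spikes,isi,t0 train length, interval (ms) and start (ms).
#' @param rate_Hz Poisson rate (Hz).
#' @return A stimulus object.
#' @name stimuli
NULL

#' @rdname stimuli
#' @export
stim_step <- function(target, amplitude_pA, onset = 0, duration = Inf) {
  stopifnot(duration >= 0, onset >= 0)
  structure(list(type = "step", target = target, amp = amplitude_pA,
                 onset = onset, duration = duration), class = "stimulus")
}

#' @rdname stimuli
#' @export
stim_noise <- function(target, mean_pA = 0, sd_pA, onset = 0, duration = Inf) {
  stopifnot(sd_pA >= 0, duration >= 0)
  structure(list(type = "noise", target = target, mean = mean_pA,
                 sd = sd_pA, onset = onset, duration = duration),
            class = "stimulus")
}

#' @rdname stimuli
#' @export
stim_spikes <- function(synapse, times) {
  stopifnot(is.numeric(times), !is.unsorted(times))
  structure(list(type = "spikes", synapse = synapse, times = times),
            class = "stimulus")
}

# `synapse` may name several slots: all receive the same spike times
# (a compound source, e.g. the AMPA and NMDA components of one pathway
# stream driven by the same presynaptic axon).

#' @rdname stimuli
#' @export
stim_train <- function(synapse, n_spikes, isi = 0.1, t0 = 0) {
  stim_spikes(synapse, synchronous_train(n_spikes, isi, t0))
}

#' @rdname stimuli
#' @export
stim_poisson <- function(synapse, rate_Hz) {
  stopifnot(all(rate_Hz >= 0))
  structure(list(type = "poisson", synapse = synapse, rate = rate_Hz),
            class = "stimulus")
}
# rate_Hz may be a vector of length n (one rate per pool neuron), so
# heterogeneous-rate experiments can share a single vectorized run.

#' Homogeneous Poisson spike train
#'
#' Samples spike times on \code{[0, duration)} by exponential inter-arrival
#' times at the given rate.
#'
#' @param rate_Hz mean rate (Hz).
#' @param duration_ms train duration (ms).
#' @param seed optional integer seed for reproducibility.
#' @return Sorted numeric vector of spike times (ms); empty at rate 0.
#' @export
poisson_train <- function(rate_Hz, duration_ms, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (rate_Hz <= 0) return(numeric(0))
  mean_isi <- 1000 / rate_Hz
  n_guess <- max(10, ceiling(duration_ms / mean_isi * 1.5 + 10))
  t <- cumsum(stats::rexp(n_guess, rate = 1 / mean_isi))
  while (t[length(t)] < duration_ms)
    t <- c(t, t[length(t)] +
             cumsum(stats::rexp(n_guess, rate = 1 / mean_isi)))
  t[t < duration_ms]
}

#' Quasi-synchronous spike train
#'
#' An arithmetic sequence of \code{n} spike times separated by \code{isi}
#' milliseconds (default 0.1 ms, i.e. quasi-simultaneous activation).
#'
#' @param n number of spikes.
#' @param isi inter-spike interval (ms).
#' @param t0 time of the first spike (ms).
#' @return Numeric vector of spike times.
#' @export
synchronous_train <- function(n, isi = 0.1, t0 = 0) {
  stopifnot(n >= 1)
  t0 + (seq_len(n) - 1) * isi
}

# comparison tolerance for event times on the step grid
.t_tol <- 1e-9

#' Simulate a neuron model (or a pool of identical neurons)
#'
#' Advances all continuous states with an explicit fixed-step integrator and
#' applies the discrete event rules in a fixed order per step: (1) due
#' delayed events (second-stage somatic reset; delayed-rectifier K onset);
#' (2) instantaneous threshold events evaluated on the state at the start of
#' the step (somatic spike; dendritic Na event); (3) delivery of presynaptic
#' spikes falling in the step interval; (4) one integration step, with
#' axial and synaptic currents evaluated inside each stage; (5) recording.
#' Event delays land on the first grid time satisfying their comparison
#' (the two-stage reset uses \code{t >= t_spike + reset_delay}; the
#' dendritic-event delays use the strict inequalities of their trigger
#' rules).
#'
#' With \code{n > 1}, \code{n} statistically independent neurons sharing the
#' same model are simulated together (vectorized across the pool): explicit
#' spike/current stimuli are shared, while Poisson and noise stimuli are
#' realized independently per neuron.
#'
#' @param model a [neuron_model()].
#' @param stimuli list of stimulus objects (see [stimuli]).
#' @param duration simulated time (ms).
#' @param dt integration step (ms); a warning is issued above 0.1 ms, the
#'   regime in which the explicit methods are accurate for these stiff-ish
#'   membrane equations.
#' @param method \code{"euler"} (default), \code{"rk2"} (midpoint) or
#'   \code{"rk4"}.
#' @param n number of independent neurons.
#' @param record character vector of state variables to record
#'   (\code{"V"}, \code{"gA"}, \code{"gNa"}, \code{"gKdr"}, \code{"s"}),
#'   or \code{"all"} or \code{"none"}.
#' @param record_stride record every \code{record_stride}-th sample.
#' @param seed master seed; mandatory when any stochastic stimulus is
#'   present.
#' @param log_events logical; collect the event log.
#' @param recurrent optional recurrent wiring between the pool neurons:
#'   \code{list(adj =, synapse =)} where \code{adj} is a list (length
#'   \code{n}) of postsynaptic neuron indices and \code{synapse} names the
#'   slot receiving recurrent input.  A somatic spike detected at the start
#'   of a step is delivered to the postsynaptic neurons \code{adj[[i]]}
#'   within that same step (an effective one-step axonal delay relative to
#'   the threshold crossing).
#' @return Object of class \code{"simulation"}: \code{time} (ms), recorded
#'   traces (matrices \code{samples x compartments} when \code{n = 1},
#'   arrays \code{samples x n x compartments} otherwise), an event log
#'   \code{data.frame(time, neuron, compartment, event)} and run metadata.
#' @export
simulate_model <- function(model, stimuli = list(), duration,
                           dt = 0.1, method = c("euler", "rk2", "rk4"),
                           n = 1L, record = "V", record_stride = 1L,
                           seed = NULL, log_events = TRUE,
                           recurrent = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(model, "neuron_model"), duration > 0, dt > 0, n >= 1)
  if (dt > 0.1)
    warning("dt = ", dt, " ms exceeds 0.1 ms; explicit integration is only ",
            "validated for dt <= 0.1 ms", call. = FALSE)
  nc <- model$n_comp
  nm <- model$comp_names
  si <- model$soma_idx
  S <- nrow(model$syn)
  n_steps <- ceiling(duration / dt - .t_tol)
  stoch <- any(vapply(stimuli, function(s) s$type %in% c("noise", "poisson"),
                      logical(1)))
  if (stoch && is.null(seed))
    stop("a master seed is required when stochastic stimuli are present",
         call. = FALSE)

  sm <- model$soma
  if (sm$reset_delay < 2 * dt || any(model$ds$t_offset_Kdr[model$ds$enabled] < 2 * dt))
    warning("dt exceeds half of an event delay; delayed events are rounded ",
            "coarsely to the grid", call. = FALSE)
  stiff <- max((model$gL + model$deg) * dt / model$Cm)
  if (method == "euler" && stiff > 1)
    warning(sprintf(paste0(
      "passive rate * dt reaches %.2f (> 1) in at least one compartment; ",
      "forward Euler may be inaccurate or unstable at dt = %g ms"),
      stiff, dt), call. = FALSE)

  # ---- precompute parameter matrices (n x nc), recycled by row -------------
  byrow <- function(v) matrix(v, n, nc, byrow = TRUE)
  CmM <- byrow(model$Cm); gLM <- byrow(model$gL); ELM <- byrow(model$EL)
  degM <- byrow(model$deg)
  ds <- model$ds
  ena <- ifelse(is.na(ds$E_Na), 0, ds$E_Na)
  ek <- ifelse(is.na(ds$E_K), 0, ds$E_K)
  ENaM <- byrow(ena); EKM <- byrow(ek)
  tauNaM <- byrow(ds$tau_Na); tauKdrM <- byrow(ds$tau_Kdr)
  ds_on <- model$dspikes_on & ds$enabled
  gbarNaM <- byrow(ifelse(ds_on, ds$gbar_Na, 0))
  gbarKdrM <- byrow(ifelse(ds_on, ds$gbar_Kdr, 0))
  VthdM <- byrow(ifelse(ds_on, ds$V_th_d, Inf))
  trefM <- byrow(ifelse(is.na(ds$t_ref_Na), Inf, ds$t_ref_Na))
  toffM <- byrow(ifelse(is.na(ds$t_offset_Kdr), Inf, ds$t_offset_Kdr))

  if (S > 0) {
    syn <- model$syn
    gfM <- matrix(syn$gbar * syn$f_syn, n, S, byrow = TRUE)
    EsynM <- matrix(syn$E_syn, n, S, byrow = TRUE)
    trM <- matrix(syn$tau_rise, n, S, byrow = TRUE)
    tdM <- matrix(syn$tau_decay, n, S, byrow = TRUE)
    satM <- matrix(as.numeric(syn$kinetics == "dual_exp_ode"), n, S,
                   byrow = TRUE)
    linM <- matrix(ifelse(syn$kinetics == "closed_form",
                          1 - syn$tau_rise / syn$tau_decay, 0), n, S,
                   byrow = TRUE)
    nmda <- which(syn$kind == "NMDA")
    syn_single <- syn$kinetics == "single_exp"
    # saturating slots are projected back into [0, 1] after each step:
    # with very large x (massed presynaptic input) an explicit step can
    # overshoot the saturation bound and oscillate
    capM <- matrix(ifelse(syn$kinetics == "dual_exp_ode", 1, Inf), n, S,
                   byrow = TRUE)
    Tmat <- matrix(0, S, nc)
    Tmat[cbind(seq_len(S), syn$target)] <- 1
    syn_tgt <- syn$target
  }

  # ---- realize stimuli -----------------------------------------------------
  ext_step <- list()    # each: list(col, amp, i0, i1)
  ext_noise <- list()   # each: list(col, vals = n x n_steps matrix, i0, i1)
  ev_step_list <- integer(0); ev_syn_list <- integer(0)
  ev_neu_list <- integer(0)  # 0 = all neurons
  spike_step <- function(times) pmin(floor(times / dt + .t_tol) + 1L, n_steps)
  for (j in seq_along(stimuli)) {
    st <- stimuli[[j]]
    stopifnot(inherits(st, "stimulus"))
    if (st$type %in% c("step", "noise")) {
      col <- match(st$target, nm)
      if (is.na(col)) stop("stimulus targets unknown compartment '",
                           st$target, "'", call. = FALSE)
      i0 <- max(1L, floor(st$onset / dt + .t_tol) + 1L)
      i1 <- min(n_steps,
                if (is.finite(st$duration))
                  floor((st$onset + st$duration) / dt + .t_tol) else n_steps)
      if (i1 < i0) next
      if (st$type == "step") {
        ext_step[[length(ext_step) + 1L]] <-
          list(col = col, amp = st$amp, i0 = i0, i1 = i1)
      } else {
        set.seed((seed + 104729L * j) %% 2147483647L)
        vals <- matrix(stats::rnorm(n * (i1 - i0 + 1L), st$mean, st$sd),
                       nrow = n)
        ext_noise[[length(ext_noise) + 1L]] <-
          list(col = col, vals = vals, i0 = i0, i1 = i1)
      }
    } else {
      if (S == 0) stop("model has no synapse slots", call. = FALSE)
      sj <- match(st$synapse, model$syn$name)
      if (anyNA(sj))
        stop("stimulus targets unknown synapse '",
             paste(st$synapse[is.na(sj)], collapse = ", "), "'",
             call. = FALSE)
      if (st$type == "spikes") {
        tt <- st$times[st$times >= 0 & st$times < duration]
        if (length(tt)) {
          stp <- spike_step(tt)
          for (s1 in sj) {
            ev_step_list <- c(ev_step_list, stp)
            ev_syn_list <- c(ev_syn_list, rep(s1, length(tt)))
            ev_neu_list <- c(ev_neu_list, rep(0L, length(tt)))
          }
        }
      } else {  # poisson, independent per neuron, shared across the
                # compound slots of one stream
        set.seed((seed + 104729L * j) %% 2147483647L)
        rates <- rep_len(st$rate, n)
        acc_step <- vector("list", n); acc_neu <- vector("list", n)
        for (ni in seq_len(n)) {
          tt <- poisson_train(rates[ni], duration)
          if (length(tt)) {
            acc_step[[ni]] <- spike_step(tt)
            acc_neu[[ni]] <- rep(ni, length(tt))
          }
        }
        stp <- unlist(acc_step); neu <- unlist(acc_neu)
        if (length(stp)) {
          for (s1 in sj) {
            ev_step_list <- c(ev_step_list, stp)
            ev_syn_list <- c(ev_syn_list, rep(s1, length(stp)))
            ev_neu_list <- c(ev_neu_list, neu)
          }
        }
      }
    }
  }
  # CSR-style pointer over presynaptic events by step
  if (length(ev_step_list)) {
    o <- order(ev_step_list)
    ev_step_list <- ev_step_list[o]
    ev_syn_list <- ev_syn_list[o]
    ev_neu_list <- ev_neu_list[o]
    ptr <- c(0L, cumsum(tabulate(ev_step_list, n_steps)))
  } else ptr <- integer(n_steps + 1L)

  # ---- state ---------------------------------------------------------------
  V <- byrow(model$EL)
  gA <- numeric(n)
  gNa <- matrix(0, n, nc); gKdr <- matrix(0, n, nc)
  fNa <- matrix(0, n, nc); fNa[, ds_on] <- 1
  fKdr <- matrix(0, n, nc)
  t_last_d <- matrix(-Inf, n, nc)
  t_last_s <- rep(-Inf, n)
  reset_due <- rep(Inf, n)
  s <- if (S > 0) matrix(0, n, S) else NULL
  x <- if (S > 0) matrix(0, n, S) else NULL

  if (!is.null(recurrent)) {
    rec_sj <- match(recurrent$synapse, model$syn$name)
    if (anyNA(rec_sj))
      stop("recurrent synapse slot not found", call. = FALSE)
    stopifnot(length(recurrent$adj) == n)
    rec_single <- model$syn$kinetics[rec_sj[1]] == "single_exp"
    rec_pending <- numeric(n)
  }

  # ---- recording -----------------------------------------------------------
  if (identical(record, "all")) record <- c("V", "gA", "gNa", "gKdr", "s")
  if (identical(record, "none")) record <- character(0)
  samp_idx <- seq(0L, n_steps, by = record_stride)
  n_samp <- length(samp_idx)
  rec <- list()
  for (v in record) {
    if (v == "gA") rec[[v]] <- matrix(NA_real_, n_samp, n)
    else if (v == "s") { if (S > 0) rec[[v]] <- array(NA_real_, c(n_samp, n, S)) }
    else rec[[v]] <- array(NA_real_, c(n_samp, n, nc))
  }
  take <- function(k) {
    for (v in names(rec)) {
      val <- switch(v, V = V, gA = gA, gNa = gNa, gKdr = gKdr, s = s)
      if (v == "gA") rec[[v]][k, ] <<- val else rec[[v]][k, , ] <<- val
    }
  }
  kk <- 1L
  if (length(rec) && samp_idx[1L] == 0L) { take(1L); kk <- 2L }

  # event log accumulators
  elog_t <- list(); elog_n <- list(); elog_c <- list(); elog_k <- list()
  push_ev <- function(tt, neuron, comp, kind) {
    i <- length(elog_t) + 1L
    elog_t[[i]] <<- rep(tt, length(neuron))
    elog_n[[i]] <<- neuron
    elog_c[[i]] <<- rep_len(comp, length(neuron))
    elog_k[[i]] <<- rep(kind, length(neuron))
  }

  # ---- right-hand side, vectorized over (neuron, compartment) -------------
  E_A <- sm$E_A; V_A <- sm$V_A; tau_A <- sm$tau_A; gbar_A <- sm$gbar_A
  rhs <- function(V, gA, gNa, gKdr, s, x, ext) {
    I <- -(V - ELM) * gLM + (V %*% model$W - V * degM) -
      gNa * (V - ENaM) - gKdr * (V - EKM)
    for (z in ext) I[, z$col] <- I[, z$col] + z$val
    if (S > 0) {
      Vt <- V[, syn_tgt, drop = FALSE]
      if (length(nmda)) {
        sig <- matrix(1, n, S)
        for (q in nmda)
          sig[, q] <- 1 / (1 + (model$syn$mg_out[q] / model$syn$mg_beta[q]) *
                             exp(-model$syn$mg_alpha[q] *
                                   (Vt[, q] - model$syn$mg_gamma[q])))
        Imat <- -gfM * s * (Vt - EsynM) * sig
      } else Imat <- -gfM * s * (Vt - EsynM)
      I <- I + Imat %*% Tmat
    }
    I[, si] <- I[, si] - gA * (V[, si] - E_A)
    list(dV = I / CmM,
         dgA = (gbar_A * abs(V[, si] - V_A) - gA) / tau_A,
         dgNa = -gNa / tauNaM,
         dgKdr = -gKdr / tauKdrM,
         ds = if (S > 0) -s / tdM + x * ((1 - s) * satM + linM) / trM,
         dx = if (S > 0) -x / trM)
  }

  # ---- main loop -----------------------------------------------------------
  for (i in seq_len(n_steps)) {
    t <- (i - 1L) * dt

    # (1) due delayed events
    due <- which(t >= reset_due - .t_tol)
    if (length(due)) {
      V[due, si] <- sm$V_reset
      reset_due[due] <- Inf
      if (log_events) push_ev(t, due, si, 2L)
    }
    kmask <- fKdr == 1 & (t - t_last_d - toffM) > .t_tol
    if (any(kmask)) {
      gKdr[kmask] <- gKdr[kmask] + gbarKdrM[kmask]
      fNa[kmask] <- 1; fKdr[kmask] <- 0
      if (log_events) {
        w <- which(kmask, arr.ind = TRUE)
        push_ev(t, w[, 1L], w[, 2L], 4L)
      }
    }

    # (2) instantaneous threshold events on the state at step start
    fire <- V[, si] > sm$V_th & (t - t_last_s - sm$reset_delay) > -.t_tol
    if (any(fire)) {
      w <- which(fire)
      V[w, si] <- sm$V_spike
      gA[w] <- gA[w] + sm$b
      t_last_s[w] <- t
      reset_due[w] <- t + sm$reset_delay
      if (log_events) push_ev(t, w, si, 1L)
      if (!is.null(recurrent))
        rec_pending <- rec_pending +
          tabulate(unlist(recurrent$adj[w]), nbins = n)
    }
    namask <- fNa == 1 & V > VthdM & (t - t_last_d - trefM) > .t_tol
    if (any(namask)) {
      gNa[namask] <- gNa[namask] + gbarNaM[namask]
      fNa[namask] <- 0; fKdr[namask] <- 1
      t_last_d[namask] <- t
      if (log_events) {
        w <- which(namask, arr.ind = TRUE)
        push_ev(t, w[, 1L], w[, 2L], 3L)
      }
    }

    # (3) presynaptic spike delivery for this step
    if (!is.null(recurrent) && any(rec_pending > 0)) {
      for (s1 in rec_sj) {
        if (rec_single) s[, s1] <- s[, s1] + rec_pending
        else x[, s1] <- x[, s1] + rec_pending
      }
      rec_pending[] <- 0
    }
    if (ptr[i + 1L] > ptr[i]) {
      idx <- (ptr[i] + 1L):ptr[i + 1L]
      sj_e <- ev_syn_list[idx]; ni_e <- ev_neu_list[idx]
      bc <- ni_e == 0L
      if (any(bc)) {  # broadcast events: one spike to every pool neuron
        for (e in which(bc)) {
          sj <- sj_e[e]
          if (syn_single[sj]) s[, sj] <- s[, sj] + 1
          else x[, sj] <- x[, sj] + 1
        }
      }
      if (any(!bc)) {
        sj1 <- sj_e[!bc]; ni1 <- ni_e[!bc]
        key <- (sj1 - 1L) * n + ni1
        if (anyDuplicated(key)) {  # same bin hit twice: aggregate counts
          agg <- rowsum(rep(1, length(key)), key)
          key <- as.integer(rownames(agg))
          cnt <- agg[, 1L]
          sj1 <- (key - 1L) %/% n + 1L; ni1 <- key - (sj1 - 1L) * n
        } else cnt <- rep(1, length(key))
        sng <- syn_single[sj1]
        if (any(sng))
          s[cbind(ni1[sng], sj1[sng])] <-
            s[cbind(ni1[sng], sj1[sng])] + cnt[sng]
        if (any(!sng))
          x[cbind(ni1[!sng], sj1[!sng])] <-
            x[cbind(ni1[!sng], sj1[!sng])] + cnt[!sng]
      }
    }

    # (4) integrate one step
    ext <- list()
    for (z in ext_step)
      if (i >= z$i0 && i <= z$i1)
        ext[[length(ext) + 1L]] <- list(col = z$col, val = z$amp)
    for (z in ext_noise)
      if (i >= z$i0 && i <= z$i1)
        ext[[length(ext) + 1L]] <- list(col = z$col,
                                        val = z$vals[, i - z$i0 + 1L])
    k1 <- rhs(V, gA, gNa, gKdr, s, x, ext)
    if (method == "euler") {
      V <- V + dt * k1$dV; gA <- gA + dt * k1$dgA
      gNa <- gNa + dt * k1$dgNa; gKdr <- gKdr + dt * k1$dgKdr
      if (S > 0) { s <- s + dt * k1$ds; x <- x + dt * k1$dx }
    } else if (method == "rk2") {
      k2 <- rhs(V + dt / 2 * k1$dV, gA + dt / 2 * k1$dgA,
                gNa + dt / 2 * k1$dgNa, gKdr + dt / 2 * k1$dgKdr,
                if (S > 0) s + dt / 2 * k1$ds, if (S > 0) x + dt / 2 * k1$dx,
                ext)
      V <- V + dt * k2$dV; gA <- gA + dt * k2$dgA
      gNa <- gNa + dt * k2$dgNa; gKdr <- gKdr + dt * k2$dgKdr
      if (S > 0) { s <- s + dt * k2$ds; x <- x + dt * k2$dx }
    } else {
      k2 <- rhs(V + dt / 2 * k1$dV, gA + dt / 2 * k1$dgA,
                gNa + dt / 2 * k1$dgNa, gKdr + dt / 2 * k1$dgKdr,
                if (S > 0) s + dt / 2 * k1$ds, if (S > 0) x + dt / 2 * k1$dx,
                ext)
      k3 <- rhs(V + dt / 2 * k2$dV, gA + dt / 2 * k2$dgA,
                gNa + dt / 2 * k2$dgNa, gKdr + dt / 2 * k2$dgKdr,
                if (S > 0) s + dt / 2 * k2$ds, if (S > 0) x + dt / 2 * k2$dx,
                ext)
      k4 <- rhs(V + dt * k3$dV, gA + dt * k3$dgA,
                gNa + dt * k3$dgNa, gKdr + dt * k3$dgKdr,
                if (S > 0) s + dt * k3$ds, if (S > 0) x + dt * k3$dx, ext)
      V <- V + dt / 6 * (k1$dV + 2 * k2$dV + 2 * k3$dV + k4$dV)
      gA <- gA + dt / 6 * (k1$dgA + 2 * k2$dgA + 2 * k3$dgA + k4$dgA)
      gNa <- gNa + dt / 6 * (k1$dgNa + 2 * k2$dgNa + 2 * k3$dgNa + k4$dgNa)
      gKdr <- gKdr + dt / 6 * (k1$dgKdr + 2 * k2$dgKdr + 2 * k3$dgKdr +
                                 k4$dgKdr)
      if (S > 0) {
        s <- s + dt / 6 * (k1$ds + 2 * k2$ds + 2 * k3$ds + k4$ds)
        x <- x + dt / 6 * (k1$dx + 2 * k2$dx + 2 * k3$dx + k4$dx)
      }
    }

    if (S > 0) s <- pmin(pmax(s, 0), capM)

    if (!all(is.finite(V))) {
      bad <- which(!is.finite(V), arr.ind = TRUE)
      stop(sprintf(
        "non-finite voltage in compartment '%s' (neuron %d) at t = %.4f ms",
        nm[bad[1, 2]], bad[1, 1], t + dt), call. = FALSE)
    }

    # (5) record
    if (kk <= n_samp && i == samp_idx[kk]) { take(kk); kk <- kk + 1L }
  }

  events <- if (length(elog_t)) {
    data.frame(time = unlist(elog_t), neuron = unlist(elog_n),
               compartment = nm[unlist(elog_c)],
               event = c("soma_spike", "soma_reset", "dspike_na",
                         "dspike_kdr")[unlist(elog_k)],
               stringsAsFactors = FALSE)
  } else {
    data.frame(time = numeric(0), neuron = integer(0),
               compartment = character(0), event = character(0),
               stringsAsFactors = FALSE)
  }

  out <- list(time = samp_idx * dt, n = n, dt = dt, duration = duration,
              method = method, seed = seed, model = model, events = events)
  for (v in names(rec)) {
    a <- rec[[v]]
    if (n == 1L && v != "gA" && length(dim(a)) == 3L)
      a <- matrix(a[, 1L, ], nrow = dim(a)[1L],
                  dimnames = list(NULL, if (dim(a)[3] == nc) nm else NULL))
    out[[v]] <- a
  }
  class(out) <- "simulation"
  out
}

#' @export
print.simulation <- function(x, ...) {
  cat(sprintf("Simulation: %.1f ms at dt = %g ms (%s), %d neuron(s)\n",
              x$duration, x$dt, x$method, x$n))
  if (nrow(x$events)) {
    cat("Events:\n")
    print(table(x$events$event))
  } else cat("No events.\n")
  invisible(x)
}

#' Plot recorded voltage traces
#'
#' @param x a \code{"simulation"} with recorded \code{V} (single neuron).
#' @param compartments names to plot (default: all).
#' @param ... passed to [graphics::matplot()].
#' @export
plot.simulation <- function(x, compartments = NULL, ...) {
  if (is.null(x$V) || x$n != 1L)
    stop("plotting requires a single-neuron simulation with recorded V",
         call. = FALSE)
  cols <- if (is.null(compartments)) colnames(x$V) else compartments
  graphics::matplot(x$time, x$V[, cols, drop = FALSE], type = "l", lty = 1,
                    xlab = "time (ms)", ylab = "membrane voltage (mV)", ...)
  graphics::legend("topright", legend = cols, lty = 1,
                   col = seq_along(cols), bty = "n", cex = 0.8)
  invisible(x)
}
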