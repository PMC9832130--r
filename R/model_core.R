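#' Surface area of an open cylindrical compartment
#'
#' Compartments are cylinders of known length and diameter; membrane area is
#' the lateral (open-cylinder) surface, excluding end caps:
#' \eqn{A = 2\pi (d/2) l}.
#'
#' @param length_um cylinder length in micrometres.
#' @param diam_um cylinder diameter in micrometres.
#' @return Area in cm^2.
#' @examples
#' cylinder_area(100, 2)   # 2 um x 100 um dendrite
#' @export
cylinder_area <- function(length_um, diam_um) {
  if (any(length_um <= 0) || any(diam_um <= 0))
    stop("invalid geometry: length and diameter must be positive", call. = FALSE)
  2 * pi * (diam_um / 2) * length_um * 1e-8  # um^2 -> cm^2
}

#' Declare a cylindrical compartment
#'
#' A compartment couples a cylinder geometry to specific (per-area) passive
#' constants, an optional spine-correction factor, an optional dendritic
#' spike mechanism and a list of synapse slots.  Specific constants use the
#' conventional units of slice electrophysiology: \code{cm_uF_cm2} in
#' uF/cm^2, \code{rm_kOhm_cm2} in kOhm cm^2, \code{ra_Ohm_cm} in Ohm cm.
#'
#' The spine factor scales both the absolute capacitance and the leak
#' conductance to account for membrane area contributed by dendritic spines
#' that are not modelled explicitly.  It defaults to 1.5 for dendrites
#' (typical corrections lie between 1.2 and 2.0) and to 1 for the soma.
#'
#' @param name unique compartment identifier.
#' @param kind \code{"soma"} or \code{"dendrite"}.
#' @param length_um,diam_um cylinder dimensions in micrometres.
#' @param cm_uF_cm2 specific membrane capacitance (uF/cm^2).
#' @param rm_kOhm_cm2 specific membrane resistivity (kOhm cm^2).
#' @param ra_Ohm_cm specific axial resistivity (Ohm cm).
#' @param EL_mV leak reversal potential (mV).
#' @param spine_factor area-correction scale in [1, 2]; \code{NULL} picks the
#'   kind-specific default.
#' @param dspike optional [dspike_params()] attaching the dendritic-spike
#'   mechanism (dendrites only).
#' @param synapses list of [synapse_params()] slots on this compartment.
#' @return An object of class \code{"compartment"}.
#' @export
compartment <- function(name, kind = c("dendrite", "soma"),
                        length_um, diam_um,
                        cm_uF_cm2 = 1, rm_kOhm_cm2 = 20, ra_Ohm_cm = 150,
                        EL_mV = -70, spine_factor = NULL,
                        dspike = NULL, synapses = list()) {
  kind <- match.arg(kind)
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("compartment name must be a non-empty string", call. = FALSE)
  if (length_um <= 0 || diam_um <= 0)
    stop("invalid geometry: length and diameter must be positive", call. = FALSE)
  if (cm_uF_cm2 <= 0 || rm_kOhm_cm2 <= 0 || ra_Ohm_cm <= 0)
    stop("specific passive constants must be strictly positive", call. = FALSE)
  if (is.null(spine_factor))
    spine_factor <- if (kind == "dendrite") 1.5 else 1
  if (spine_factor < 1 || spine_factor > 2)
    stop("spine_factor must lie in [1, 2]", call. = FALSE)
  if (!is.null(dspike)) {
    if (kind == "soma")
      stop("dendritic spike mechanism cannot be attached to the soma",
           call. = FALSE)
    stopifnot(inherits(dspike, "dspike_params"))
  }
  if (length(synapses)) {
    ok <- vapply(synapses, inherits, logical(1), what = "synapse_params")
    if (!all(ok)) stop("synapses must be a list of synapse_params()", call. = FALSE)
  }
  structure(list(name = name, kind = kind,
                 length_um = length_um, diam_um = diam_um,
                 cm_uF_cm2 = cm_uF_cm2, rm_kOhm_cm2 = rm_kOhm_cm2,
                 ra_Ohm_cm = ra_Ohm_cm, EL_mV = EL_mV,
                 spine_factor = spine_factor,
                 dspike = dspike, synapses = synapses),
            class = "compartment")
}

#' Absolute passive properties of a compartment
#'
#' Converts specific constants to absolute ones through the membrane area:
#' \eqn{C_m = c_m A}, \eqn{g_L = A / r_m}, both multiplied by the spine
#' factor.  The membrane time constant \eqn{\tau_m = C_m/g_L = c_m r_m} is
#' independent of geometry and of the spine factor.
#'
#' @param comp a [compartment()].
#' @return Named numeric vector with \code{Cm_pF} and \code{gL_nS}.
#' @export
absolute_passive <- function(comp) {
  stopifnot(inherits(comp, "compartment"))
  A <- cylinder_area(comp$length_um, comp$diam_um)           # cm^2
  Cm <- comp$cm_uF_cm2 * A * comp$spine_factor * 1e6         # uF -> pF
  gL <- A / (comp$rm_kOhm_cm2 * 1e3) * comp$spine_factor * 1e9  # S -> nS
  c(Cm_pF = Cm, gL_nS = gL)
}

#' Axial coupling conductance between two adjacent compartments
#'
#' Two conventions are supported.  The half-cylinder method takes the
#' longitudinal resistance between the two compartment centres,
#' \deqn{R = \frac{1}{2}\left(\frac{r_a l^k}{\pi (d^k/2)^2} +
#'                            \frac{r_a l^i}{\pi (d^i/2)^2}\right),}
#' and is symmetric in the two compartments.  The full-cylinder method uses
#' the whole longitudinal resistance of a single compartment,
#' \eqn{R = r_a l / \pi (d/2)^2}; it is appropriate when the model has few
#' compartments and the compartments adjacent to the soma are strongly
#' coupled.  The full-cylinder geometry is taken from \code{distal} (the
#' child compartment of the edge); this choice is a package convention, and
#' an explicit coupling override on the model can replace it.
#'
#' @param proximal,distal the two adjacent [compartment()]s; for the
#'   full-cylinder method \code{distal} supplies the geometry.
#' @param method \code{"half_cylinder"} (default) or \code{"full_cylinder"}.
#' @return Coupling conductance in nS (identical in both directions).
#' @examples
#' a <- compartment("a", "dendrite", length_um = 100, diam_um = 1)
#' b <- compartment("b", "dendrite", length_um = 200, diam_um = 2)
#' coupling_conductance(a, b)                      # half-cylinder
#' coupling_conductance(a, b, "full_cylinder")     # uses b's geometry
#' @export
coupling_conductance <- function(proximal, distal,
                                 method = c("half_cylinder", "full_cylinder")) {
  method <- match.arg(method)
  stopifnot(inherits(proximal, "compartment"), inherits(distal, "compartment"))
  r_long <- function(cc) {
    l_cm <- cc$length_um * 1e-4
    r_cm <- cc$diam_um / 2 * 1e-4
    if (r_cm <= 0) stop("invalid geometry: zero diameter", call. = FALSE)
    cc$ra_Ohm_cm * l_cm / (pi * r_cm^2)  # Ohm
  }
  R <- switch(method,
              full_cylinder = r_long(distal),
              half_cylinder = 0.5 * (r_long(proximal) + r_long(distal)))
  1 / R * 1e9  # Ohm^-1 -> nS
}

#' Somatic spiking parameters
#'
#' Parameters of the leaky integrate-and-fire soma with conductance-based
#' adaptation and a two-stage reset.  When the somatic voltage crosses
#' \code{V_th} the voltage is set instantly to \code{V_spike} (emulating the
#' biological spike amplitude) and the adaptation conductance is incremented
#' by \code{b}; after \code{reset_delay} milliseconds the voltage is reset to
#' \code{V_reset}.  The adaptation conductance relaxes towards
#' \eqn{\bar g_A |V - V_A|} with time constant \code{tau_A} and enters the
#' membrane equation as \eqn{-g_A (V - E_A)}.
#'
#' @param V_th,V_spike,V_reset threshold, spike-plateau and reset voltages
#'   (mV); must satisfy \code{V_spike > V_th > V_reset}.
#' @param reset_delay plateau duration before the second reset (ms).
#' @param tau_A adaptation time constant (ms).
#' @param gbar_A maximum (subthreshold) adaptation conductance (nS).
#' @param b spike-triggered adaptation increment (nS).
#' @param E_A adaptation reversal potential (mV).
#' @param V_A reference voltage of the subthreshold adaptation drive (mV);
#'   \code{NULL} means "use the somatic leak reversal", resolved when the
#'   model is built.
#' @return Object of class \code{"soma_params"}.
#' @export
soma_params <- function(V_th = -50, V_spike = 40, V_reset = -55,
                        reset_delay = 0.5, tau_A = 100, gbar_A = 0,
                        b = 0, E_A = -70, V_A = NULL) {
  if (!(V_spike > V_th && V_th > V_reset))
    stop("require V_spike > V_th > V_reset", call. = FALSE)
  if (reset_delay <= 0 || tau_A <= 0 || gbar_A < 0 || b < 0)
    stop("reset_delay, tau_A must be > 0; gbar_A, b must be >= 0",
         call. = FALSE)
  structure(list(V_th = V_th, V_spike = V_spike, V_reset = V_reset,
                 reset_delay = reset_delay, tau_A = tau_A, gbar_A = gbar_A,
                 b = b, E_A = E_A, V_A = V_A),
            class = "soma_params")
}

#' Dendritic spike (Na+/K_dr) mechanism parameters
#'
#' The dendritic spike is modelled phenomenologically: when the dendritic
#' voltage crosses \code{V_th_d} (outside the refractory period, with the
#' mechanism armed) the sodium conductance is stepped up by \code{gbar_Na}
#' and decays exponentially with \code{tau_Na}; after \code{t_offset_Kdr}
#' milliseconds a delayed-rectifier potassium conductance is stepped up by
#' \code{gbar_Kdr} and decays with \code{tau_Kdr}, repolarizing the branch.
#' A new sodium event requires \code{t_ref_Na} milliseconds to have elapsed
#' since the previous one.  \code{t_offset_Kdr < t_ref_Na} is enforced so
#' the two-flag state machine always re-arms before the refractory window
#' ends.
#'
#' @param gbar_Na,gbar_Kdr conductance increments per event (nS).
#' @param E_Na,E_K sodium and potassium reversal potentials (mV).
#' @param tau_Na,tau_Kdr conductance decay time constants (ms).
#' @param V_th_d dendritic spike threshold (mV).
#' @param t_ref_Na sodium refractory period (ms).
#' @param t_offset_Kdr delay of the potassium event after the sodium event
#'   (ms); must be shorter than \code{t_ref_Na}.
#' @param enabled logical; a disabled mechanism never fires.
#' @return Object of class \code{"dspike_params"}.
#' @export
dspike_params <- function(gbar_Na, gbar_Kdr, E_Na = 70, E_K = -89,
                          tau_Na = 1.5, tau_Kdr = 3, V_th_d = -35,
                          t_ref_Na = 5, t_offset_Kdr = 1, enabled = TRUE) {
  if (gbar_Na < 0 || gbar_Kdr < 0)
    stop("conductance increments must be >= 0", call. = FALSE)
  if (tau_Na <= 0 || tau_Kdr <= 0 || t_ref_Na <= 0 || t_offset_Kdr <= 0)
    stop("time constants and delays must be strictly positive", call. = FALSE)
  if (t_offset_Kdr >= t_ref_Na)
    stop("t_offset_Kdr must be smaller than t_ref_Na ",
         "(the K event must fire before the mechanism re-arms)",
         call. = FALSE)
  if (!(E_Na > V_th_d && V_th_d > E_K))
    stop("require E_Na > V_th_d > E_K", call. = FALSE)
  structure(list(gbar_Na = gbar_Na, gbar_Kdr = gbar_Kdr, E_Na = E_Na,
                 E_K = E_K, tau_Na = tau_Na, tau_Kdr = tau_Kdr,
                 V_th_d = V_th_d, t_ref_Na = t_ref_Na,
                 t_offset_Kdr = t_offset_Kdr, enabled = isTRUE(enabled)),
            class = "dspike_params")
}

# Internal: connected-tree check on an edge list over n named nodes.
check_tree <- function(names, edges) {
  n <- length(names)
  if (n == 1L) {
    if (length(edges)) stop("single-compartment model cannot have edges",
                            call. = FALSE)
    return(invisible(TRUE))
  }
  em <- do.call(rbind, lapply(edges, function(e) {
    if (length(e) != 2L) stop("each edge must name two compartments",
                              call. = FALSE)
    m <- match(e, names)
    if (anyNA(m)) stop("edge references unknown compartment: ",
                       paste(e[is.na(m)], collapse = ", "), call. = FALSE)
    m
  }))
  if (nrow(em) != n - 1L)
    stop("compartment graph must be a tree: expected ", n - 1L,
         " edges, got ", nrow(em), call. = FALSE)
  adj <- vector("list", n)
  for (i in seq_len(nrow(em))) {
    a <- em[i, 1]; b <- em[i, 2]
    if (a == b) stop("self-edge on compartment '", names[a], "'", call. = FALSE)
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  seen <- logical(n); queue <- 1L; seen[1L] <- TRUE
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    nb <- adj[[v]][!seen[adj[[v]]]]
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  if (!all(seen))
    stop("compartment graph is disconnected (or contains a cycle): ",
         "unreachable compartments: ",
         paste(names[!seen], collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

#' Assemble a neuron model
#'
#' Validates a declarative set of compartments and edges (which must form a
#' connected tree with exactly one soma), converts all specific constants to
#' absolute capacitances and conductances, and computes the symmetric axial
#' coupling matrix.  Edge order \code{c(proximal, distal)} designates which
#' compartment supplies the geometry under the full-cylinder method.
#'
#' @param compartments list of [compartment()] objects.
#' @param edges list of length-2 character vectors \code{c(proximal, distal)}.
#' @param soma a [soma_params()] object for the spiking mechanism.
#' @param coupling_method default method for [coupling_conductance()].
#' @param coupling_overrides optional named list \code{"a|b" = nS} replacing
#'   the computed conductance of the edge between compartments \code{a} and
#'   \code{b} (order irrelevant); useful for the small manual corrections
#'   sometimes needed to reach realistic attenuation.
#' @return Object of class \code{"neuron_model"}: per-compartment absolute
#'   passive parameters, coupling matrix \code{W} (nS), dendritic-spike
#'   parameter table, synapse table and index maps.
#' @export
neuron_model <- function(compartments, edges = list(),
                         soma = soma_params(),
                         coupling_method = c("half_cylinder", "full_cylinder"),
                         coupling_overrides = NULL) {
  coupling_method <- match.arg(coupling_method)
  stopifnot(is.list(compartments), length(compartments) >= 1L)
  ok <- vapply(compartments, inherits, logical(1), what = "compartment")
  if (!all(ok)) stop("compartments must be compartment() objects", call. = FALSE)
  nm <- vapply(compartments, `[[`, character(1), "name")
  if (anyDuplicated(nm))
    stop("duplicate compartment names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  kinds <- vapply(compartments, `[[`, character(1), "kind")
  if (sum(kinds == "soma") != 1L)
    stop("model must contain exactly one soma compartment (found ",
         sum(kinds == "soma"), ")", call. = FALSE)
  stopifnot(inherits(soma, "soma_params"))
  check_tree(nm, edges)

  n <- length(compartments)
  pass <- t(vapply(compartments, absolute_passive, numeric(2)))
  soma_idx <- which(kinds == "soma")

  W <- matrix(0, n, n, dimnames = list(nm, nm))
  for (e in edges) {
    i <- match(e[1], nm); k <- match(e[2], nm)
    g <- coupling_conductance(compartments[[i]], compartments[[k]],
                              coupling_method)
    W[i, k] <- W[k, i] <- g
  }
  if (!is.null(coupling_overrides)) {
    for (key in names(coupling_overrides)) {
      ab <- strsplit(key, "|", fixed = TRUE)[[1]]
      i <- match(ab[1], nm); k <- match(ab[2], nm)
      if (anyNA(c(i, k)) || W[i, k] == 0)
        stop("coupling override '", key, "' does not match an edge",
             call. = FALSE)
      W[i, k] <- W[k, i] <- coupling_overrides[[key]]
    }
  }

  # per-compartment dendritic-spike parameter table (soma row disabled)
  ds_fields <- c("gbar_Na", "gbar_Kdr", "E_Na", "E_K", "tau_Na", "tau_Kdr",
                 "V_th_d", "t_ref_Na", "t_offset_Kdr")
  ds <- as.data.frame(setNames(rep(list(rep(NA_real_, n)), length(ds_fields)),
                               ds_fields))
  ds$enabled <- rep(FALSE, n)
  for (i in seq_len(n)) {
    dp <- compartments[[i]]$dspike
    if (!is.null(dp)) {
      for (f in ds_fields) ds[[f]][i] <- dp[[f]]
      ds$enabled[i] <- dp$enabled
    }
  }
  # benign fill so vectorized decay terms never divide by NA
  ds$tau_Na[is.na(ds$tau_Na)] <- 1
  ds$tau_Kdr[is.na(ds$tau_Kdr)] <- 1
  rownames(ds) <- nm

  syn <- build_synapse_table(compartments, nm)

  if (is.null(soma$V_A)) soma$V_A <- compartments[[soma_idx]]$EL_mV

  structure(list(
    compartments = setNames(compartments, nm),
    comp_names = nm,
    n_comp = n,
    kind = kinds,
    soma_idx = soma_idx,
    soma = soma,
    Cm = unname(pass[, 1]),
    gL = unname(pass[, 2]),
    EL = vapply(compartments, `[[`, numeric(1), "EL_mV"),
    W = W,
    deg = colSums(W),
    edges = edges,
    coupling_method = coupling_method,
    coupling_overrides = coupling_overrides,
    ds = ds,
    dspikes_on = TRUE,
    syn = syn
  ), class = "neuron_model")
}

# Internal: flatten per-compartment synapse slots into one table.
build_synapse_table <- function(compartments, nm) {
  rows <- list()
  for (i in seq_along(compartments)) {
    for (sp in compartments[[i]]$synapses) {
      pk <- syn_peak_norm(sp)
      rows[[length(rows) + 1L]] <- data.frame(
        name = sp$name, target = i, kind = sp$kind, gbar = sp$gbar,
        E_syn = sp$E_syn, tau_rise = sp$tau_rise, tau_decay = sp$tau_decay,
        kinetics = sp$kinetics, f_syn = pk["f_syn"],
        mg_alpha = if (is.null(sp$mg)) NA_real_ else sp$mg$alpha,
        mg_beta = if (is.null(sp$mg)) NA_real_ else sp$mg$beta,
        mg_gamma = if (is.null(sp$mg)) NA_real_ else sp$mg$gamma,
        mg_out = if (is.null(sp$mg)) NA_real_ else sp$mg$mg_out,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(name = character(), target = integer(),
                      kind = character(), gbar = numeric(), E_syn = numeric(),
                      tau_rise = numeric(), tau_decay = numeric(),
                      kinetics = character(), f_syn = numeric(),
                      mg_alpha = numeric(), mg_beta = numeric(),
                      mg_gamma = numeric(), mg_out = numeric(),
                      stringsAsFactors = FALSE))
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  if (anyDuplicated(tab$name))
    stop("duplicate synapse names: ",
         paste(unique(tab$name[duplicated(tab$name)]), collapse = ", "),
         call. = FALSE)
  tab
}

#' Enable or disable all dendritic spike mechanisms
#'
#' With dendritic spikes disabled the threshold mechanism never fires and the
#' Na+/K_dr conductances stay at zero; all other dynamics are unchanged, so
#' the model is trace-identical to one built without any dendritic-spike
#' parameters.  (If toggled mid-run through a fresh simulation, residual
#' conductances from a previous run are not carried over; simulations always
#' start from rest.)
#'
#' @param model a [neuron_model()].
#' @param enabled logical.
#' @return The modified model.
#' @export
set_dspikes <- function(model, enabled) {
  stopifnot(inherits(model, "neuron_model"))
  model$dspikes_on <- isTRUE(enabled)
  model
}

#' Block synapses of one receptor kind
#'
#' Emulates a pharmacological blocker by setting the peak conductance of
#' every synapse slot of the given kind to zero (e.g. NMDA antagonists).
#'
#' @param model a [neuron_model()].
#' @param kind receptor kind to block.
#' @return The modified model.
#' @export
block_synapses <- function(model, kind = c("NMDA", "AMPA", "GABA")) {
  kind <- match.arg(kind)
  stopifnot(inherits(model, "neuron_model"))
  model$syn$gbar[model$syn$kind == kind] <- 0
  model$compartments <- lapply(model$compartments, function(cc) {
    cc$synapses <- lapply(cc$synapses, function(sp) {
      if (sp$kind == kind) sp$gbar <- 0
      sp
    })
    cc
  })
  model
}

#' @export
print.neuron_model <- function(x, ...) {
  cat("Reduced compartmental neuron model\n")
  cat(sprintf("  %d compartments (soma: %s), coupling: %s\n",
              x$n_comp, x$comp_names[x$soma_idx], x$coupling_method))
  tab <- data.frame(name = x$comp_names, kind = x$kind,
                    Cm_pF = round(x$Cm, 3), gL_nS = round(x$gL, 4),
                    EL_mV = x$EL, dspike = x$ds$enabled)
  print(tab, row.names = FALSE)
  if (nrow(x$syn))
    cat(sprintf("  %d synapse slot(s): %s\n", nrow(x$syn),
                paste(x$syn$name, collapse = ", ")))
  if (!x$dspikes_on && any(x$ds$enabled))
    cat("  [dendritic spikes globally disabled]\n")
  invisible(x)
}
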