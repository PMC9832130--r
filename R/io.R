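#' Read and write neuron-model documents (JSON)
#'
#' A model document is a JSON object with a \code{schema_version} (currently
#' 1), a list of compartments (geometry in micrometres, specific constants
#' in uF/cm^2, kOhm cm^2, Ohm cm, voltages in mV), the edge list, the
#' somatic spiking parameters, the coupling method and optional overrides
#' (nS), and a free-text provenance note.  Units are embedded in the field
#' names so documents are self-describing.  \code{read_model()} validates
#' the document and returns an assembled [neuron_model()];
#' \code{write_model()} serializes one so that a read/write round trip
#' reproduces the model exactly.
#'
#' @param model a [neuron_model()].
#' @param path file path.
#' @param provenance free-text note stored in the document.
#' @param strict logical; unknown fields are an error when TRUE (default),
#'   a warning otherwise.
#' @return \code{read_model()}: a [neuron_model()]; \code{write_model()}:
#'   the path, invisibly.
#' @name model_io
NULL

.schema_version <- 1L

#' @rdname model_io
#' @export
write_model <- function(model, path, provenance = "") {
  stopifnot(inherits(model, "neuron_model"))
  comp_doc <- lapply(model$compartments, function(cc) {
    doc <- list(name = cc$name, kind = cc$kind,
                length_um = cc$length_um, diam_um = cc$diam_um,
                cm_uF_cm2 = cc$cm_uF_cm2, rm_kOhm_cm2 = cc$rm_kOhm_cm2,
                ra_Ohm_cm = cc$ra_Ohm_cm, EL_mV = cc$EL_mV,
                spine_factor = cc$spine_factor)
    if (!is.null(cc$dspike))
      doc$dspike <- unclass(cc$dspike)
    if (length(cc$synapses))
      doc$synapses <- lapply(cc$synapses, function(sp) {
        sd <- list(kind = sp$kind, gbar_nS = sp$gbar, name = sp$name,
                   E_syn_mV = sp$E_syn, tau_rise_ms = sp$tau_rise,
                   tau_decay_ms = sp$tau_decay, kinetics = sp$kinetics)
        if (!is.null(sp$mg)) sd$mg <- unclass(sp$mg)
        sd
      })
    doc
  })
  doc <- list(schema_version = .schema_version,
              compartments = unname(comp_doc),
              edges = lapply(model$edges, as.character),
              soma_params = unclass(model$soma),
              coupling_method = model$coupling_method,
              provenance = provenance)
  if (!is.null(model$coupling_overrides))
    doc$coupling_overrides_nS <- model$coupling_overrides
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

# Internal: check a document node for unexpected fields.
check_fields <- function(node, known, where, strict) {
  extra <- setdiff(names(node), known)
  if (length(extra)) {
    msg <- paste0("unknown field(s) at ", where, ": ",
                  paste(extra, collapse = ", "))
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
}

#' @rdname model_io
#' @export
read_model <- function(path, strict = TRUE) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(doc$schema_version) || doc$schema_version != .schema_version)
    stop("unsupported model document schema version: ",
         if (is.null(doc$schema_version)) "missing" else doc$schema_version,
         call. = FALSE)
  check_fields(doc, c("schema_version", "compartments", "edges",
                      "soma_params", "coupling_method",
                      "coupling_overrides_nS", "provenance"),
               "/", strict)
  need <- function(node, field, where) {
    if (is.null(node[[field]]))
      stop("missing required field at ", where, "/", field, call. = FALSE)
    node[[field]]
  }
  comps <- lapply(seq_along(doc$compartments), function(i) {
    cd <- doc$compartments[[i]]
    where <- paste0("/compartments/", i)
    check_fields(cd, c("name", "kind", "length_um", "diam_um", "cm_uF_cm2",
                       "rm_kOhm_cm2", "ra_Ohm_cm", "EL_mV", "spine_factor",
                       "dspike", "synapses"), where, strict)
    dsp <- NULL
    if (!is.null(cd$dspike)) {
      dd <- cd$dspike
      check_fields(dd, c("gbar_Na", "gbar_Kdr", "E_Na", "E_K", "tau_Na",
                         "tau_Kdr", "V_th_d", "t_ref_Na", "t_offset_Kdr",
                         "enabled"), paste0(where, "/dspike"), strict)
      dsp <- dspike_params(gbar_Na = dd$gbar_Na, gbar_Kdr = dd$gbar_Kdr,
                           E_Na = dd$E_Na, E_K = dd$E_K,
                           tau_Na = dd$tau_Na, tau_Kdr = dd$tau_Kdr,
                           V_th_d = dd$V_th_d, t_ref_Na = dd$t_ref_Na,
                           t_offset_Kdr = dd$t_offset_Kdr,
                           enabled = dd$enabled)
    }
    syns <- lapply(seq_along(cd$synapses), function(j) {
      sd <- cd$synapses[[j]]
      sw <- paste0(where, "/synapses/", j)
      check_fields(sd, c("kind", "gbar_nS", "name", "E_syn_mV",
                         "tau_rise_ms", "tau_decay_ms", "kinetics", "mg"),
                   sw, strict)
      mg <- if (!is.null(sd$mg))
        mg_params(alpha = sd$mg$alpha, beta = sd$mg$beta,
                  gamma = sd$mg$gamma, mg_out = sd$mg$mg_out)
      synapse_params(kind = sd$kind, gbar = need(sd, "gbar_nS", sw),
                     name = need(sd, "name", sw), E_syn = sd$E_syn_mV,
                     tau_rise = sd$tau_rise_ms, tau_decay = sd$tau_decay_ms,
                     kinetics = sd$kinetics, mg = mg)
    })
    compartment(name = need(cd, "name", where),
                kind = need(cd, "kind", where),
                length_um = need(cd, "length_um", where),
                diam_um = need(cd, "diam_um", where),
                cm_uF_cm2 = cd$cm_uF_cm2 %||% 1,
                rm_kOhm_cm2 = cd$rm_kOhm_cm2 %||% 20,
                ra_Ohm_cm = cd$ra_Ohm_cm %||% 150,
                EL_mV = cd$EL_mV %||% -70,
                spine_factor = cd$spine_factor,
                dspike = dsp, synapses = syns)
  })
  sp <- doc$soma_params %||% list()
  soma <- soma_params(V_th = sp$V_th %||% -50,
                      V_spike = sp$V_spike %||% 40,
                      V_reset = sp$V_reset %||% -55,
                      reset_delay = sp$reset_delay %||% 0.5,
                      tau_A = sp$tau_A %||% 100,
                      gbar_A = sp$gbar_A %||% 0,
                      b = sp$b %||% 0,
                      E_A = sp$E_A %||% -70,
                      V_A = sp$V_A)
  neuron_model(comps,
               edges = lapply(doc$edges, unlist),
               soma = soma,
               coupling_method = doc$coupling_method %||% "half_cylinder",
               coupling_overrides = doc$coupling_overrides_nS)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write simulation results to plain-text files
#'
#' Writes the recorded voltage traces (CSV, one \code{time_ms} column then
#' one \code{<compartment>_V_mV} column each), the event log (CSV) and a
#' JSON metadata manifest (duration, dt, method, seed, package version)
#' sufficient to re-run the simulation.
#'
#' @param sim a \code{"simulation"} (single neuron for traces).
#' @param dir output directory (created if needed).
#' @param stem file-name stem.
#' @return Invisibly, the written file paths.
#' @export
write_simulation <- function(sim, dir, stem = "simulation") {
  stopifnot(inherits(sim, "simulation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  if (!is.null(sim$V) && sim$n == 1L) {
    tr <- data.frame(time_ms = sim$time)
    for (cn in colnames(sim$V)) tr[[paste0(cn, "_V_mV")]] <- sim$V[, cn]
    p <- file.path(dir, paste0(stem, "_traces.csv"))
    utils::write.csv(tr, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  p <- file.path(dir, paste0(stem, "_events.csv"))
  utils::write.csv(sim$events, p, row.names = FALSE)
  paths <- c(paths, p)
  meta <- list(duration_ms = sim$duration, dt_ms = sim$dt,
               method = sim$method, n = sim$n, seed = sim$seed,
               package_version = as.character(utils::packageVersion("dendsim")))
  p <- file.path(dir, paste0(stem, "_manifest.json"))
  jsonlite::write_json(meta, p, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  paths <- c(paths, p)
  invisible(paths)
}
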