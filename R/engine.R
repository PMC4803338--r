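# R-side driver of the compiled integrator: simulation specs, probe
# resolution, settled initialization and the recording container.

#' Simulation specification
#'
#' @param duration Simulated time after t = 0, ms.
#' @param dt Integration time step, ms (default 0.1).
#' @param probes Named list of probes; each entry is `list(site =
#'   site_address, qty = "V"|"ICa"|"Ca"|"gsyn")`.  Default: [probe_set()].
#' @param v_init Initialization potential, mV.
#' @param settle Settling time simulated before t = 0 so every trial starts
#'   from the relaxed resting state, ms.
#' @return A `sim_spec`.
#' @export
simulation_spec <- function(duration, dt = 0.1, probes = probe_set(),
                            v_init = -70, settle = 200) {
  stopifnot(dt > 0, duration >= dt, settle >= 0)
  structure(list(duration = duration, dt = dt, probes = probes,
                 v_init = v_init, settle = settle), class = "sim_spec")
}

#' Standard probe set
#'
#' Voltage in the basal dendrite (75 um), the oblique dendrite (370 um), the
#' apical tuft (650 um), the soma and the axon; calcium current and calcium
#' concentration at the tuft site.
#'
#' @return Named list of probes for [simulation_spec()].
#' @export
probe_set <- function() {
  list(
    soma = list(site = site("soma", 0.5), qty = "V"),
    axon = list(site = site("axon", 0.5), qty = "V"),
    basal75 = list(site = site_um(75, "basal"), qty = "V"),
    oblique370 = list(site = site_um(370, "oblique"), qty = "V"),
    tuft650 = list(site = site_um(650, "apical"), qty = "V"),
    tuft650_ica = list(site = site_um(650, "apical"), qty = "ICa"),
    tuft650_ca = list(site = site_um(650, "apical"), qty = "Ca")
  )
}

.qty_code <- function(q) {
  code <- match(q, c("V", "ICa", "Ca", "gsyn")) - 1L
  if (any(is.na(code))) stop("unknown probe quantity")
  code
}

# translate a protocol into the stim list consumed by the integrator
.build_stim <- function(model, proto, interneuron = NULL) {
  stopifnot(inherits(proto, "stim_protocol"))
  steps <- matrix(numeric(0), 0, 4)
  synapses <- list()
  for (e in proto$events) {
    seg0 <- .seg_index(model, e$site) - 1L
    if (inherits(e, "step_event")) {
      steps <- rbind(steps, c(seg0, e$onset, e$dur_ms, e$amp_nA))
    } else {
      synapses[[length(synapses) + 1]] <-
        list(seg = seg0, type = e$type, tau_r = e$tau_r, tau_d = e$tau_d,
             gmax_uS = e$gmax_nS * 1e-3, erev = e$e_rev, onsets = e$onsets)
    }
  }
  list(steps = steps, synapses = synapses, interneuron = interneuron)
}

#' Simulate a stimulation protocol
#'
#' Integrates the model with an implicit scheme at the spec's time step.  The
#' state at t = 0 is the relaxed resting state: the model is initialized at
#' `v_init` with gates at steady state and simulated for `settle` ms without
#' input (this settling run is cached on the model, so repeated protocol runs
#' pay for it once).
#'
#' @param model A `pyr_model`.
#' @param proto A `stim_protocol` (all event times are relative to t = 0).
#' @param spec A `sim_spec`.
#' @return A `recording`: list with `time` (ms), `series` (named list of
#'   numeric vectors; mV, mA/cm^2, mM or uS according to the probe), `rest`
#'   (per-probe value at t = 0) and metadata.
#' @export
simulate_protocol <- function(model, proto, spec) {
  stopifnot(inherits(model, "pyr_model"), inherits(spec, "sim_spec"))
  for (e in proto$events) {
    tmax <- if (inherits(e, "step_event")) e$onset else max(e$onsets)
    if (tmax > spec$duration)
      stop("protocol event at ", tmax, " ms falls outside the ",
           spec$duration, " ms duration")
  }
  probes <- spec$probes
  seg0 <- vapply(probes, function(p) .seg_index(model, p$site) - 1L, integer(1))
  qty <- vapply(probes, function(p) .qty_code(p$qty), integer(1))
  st <- if (spec$settle > 0)
    .settled_state(model, spec$dt, spec$settle, spec$v_init) else NULL
  stim <- .build_stim(model, proto)
  res <- .engine_run(model$cpp, stim,
                     list(dt = spec$dt, duration = spec$duration,
                          v_init = spec$v_init,
                          probe_seg = as.integer(seg0),
                          probe_qty = as.integer(qty)),
                     st)
  series <- stats::setNames(
    lapply(seq_along(probes), function(j) res$series[, j]), names(probes))
  structure(list(time = res$time, series = series,
                 rest = vapply(series, function(x) x[1], numeric(1)),
                 probes = probes, spec = spec, protocol = proto,
                 in_spike_time = res$in_spike_time),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat("<recording>", length(x$time), "samples,",
      length(x$series), "probes:", paste(names(x$series), collapse = ", "),
      "\n")
  invisible(x)
}

#' Recording as a tidy data frame
#'
#' @param x A `recording`.
#' @param ... Unused.
#' @return Long-format data frame: `time`, `probe`, `value`.
#' @export
as.data.frame.recording <- function(x, ...) {
  do.call(rbind, lapply(names(x$series), function(nm)
    data.frame(time = x$time, probe = nm, value = x$series[[nm]])))
}

#' Write a recording to CSV (long format)
#'
#' @param rec A `recording`.
#' @param file Output path.
#' @export
write_recording_csv <- function(rec, file) {
  utils::write.csv(as.data.frame(rec), file, row.names = FALSE)
  invisible(file)
}
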