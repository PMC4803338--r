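# Two-cell feedforward-inhibition (FFI) microcircuit: a common excitatory
# source drives both the pyramidal cell (8 synapses distributed along the
# apical trunk, 20 nS total) and a single-compartment fast-spiking
# interneuron (Hodgkin-Huxley Na/K dynamics with a temperature factor of 5);
# the interneuron's first spike triggers, after a lumped axonal+synaptic
# dead time, a shunting conductance on the pyramidal dendrite.  A slowed
# variant scales the sodium opening rates by 0.1 and the closing rates by
# 0.2.  The disinhibitory interneuron of the full motif is represented by
# the boolean `in_active` switch (tonic disinhibition).

#' Fast-spiking interneuron model parameters
#'
#' Single compartment with transient Na (instantaneous-like activation m^3 h)
#' and delayed-rectifier K (n^4); rates carry a temperature/scaling factor
#' phi = 5.  The `"slow"` variant multiplies the sodium opening rates by 0.1
#' and the closing rates by 0.2, which delays spike initiation without
#' abolishing it.
#'
#' @param variant `"fast"` or `"slow"`.
#' @param diam_um Compartment diameter (sphere-equivalent cylinder), um.
#' @return List of interneuron parameters.
#' @export
interneuron_model <- function(variant = c("fast", "slow"), diam_um = 150) {
  variant <- match.arg(variant)
  scales <- if (variant == "fast") c(1, 1) else c(0.1, 0.2)
  area <- pi * (diam_um * 1e-4)^2   # cylinder with L = diam
  list(variant = variant,
       area_cm2 = area,
       cm = 1,                       # uF/cm^2
       gna_dens = 0.035, gk_dens = 0.009, gl_dens = 1e-4,  # S/cm^2
       el = -65, ena = 55, ek = -90, phi = 5,
       a_scale = scales[1], b_scale = scales[2],
       thresh = 0)
}

#' Assemble the feedforward-inhibition circuit
#'
#' @param model Pyramidal `pyr_model`.
#' @param interneuron An [interneuron_model()].
#' @param in_site Dendritic target of the interneuron's shunting synapse.
#' @param in_gmax_nS Peak conductance of the IN->PC synapse, nS.
#' @param delay_ms Lumped dead time between the interneuron spike and the
#'   onset of the IN->PC conductance (axonal conduction + transmission), ms.
#' @param ex_in_gmax_nS Conductance of the EX->IN synapse (300 nS: the
#'   common source drives the interneuron suprathreshold with a short
#'   latency).
#' @param ex_pc_total_nS Total conductance of the EX->PC distributed drive.
#' @return An `ffi_circuit` object.
#' @export
ffi_circuit <- function(model, interneuron = interneuron_model("fast"),
                        in_site = site_um(90, "apical"), in_gmax_nS = 50,
                        delay_ms = 1, ex_in_gmax_nS = 300,
                        ex_pc_total_nS = 20) {
  structure(list(model = model, interneuron = interneuron,
                 in_site = in_site, in_gmax_nS = in_gmax_nS,
                 delay_ms = delay_ms, ex_in_gmax_nS = ex_in_gmax_nS,
                 ex_pc_total_nS = ex_pc_total_nS),
            class = "ffi_circuit")
}

#' Run one feedforward-inhibition trial
#'
#' The excitatory source fires at `t0`, driving the pyramidal trunk synapses
#' and the interneuron.  If the interneuron is active and spikes, its
#' shunting synapse on the pyramidal dendrite is activated `delay_ms` after
#' the spike.  Silencing the interneuron (`in_active = FALSE`, the
#' disinhibition paradigm) makes the trial identical to the no-inhibition
#' single-cell trial.
#'
#' @param circuit An [ffi_circuit()].
#' @param in_active Is the feedforward interneuron active?
#' @param t0 Source event time, ms.
#' @param duration Trial duration, ms.
#' @param probes Probe list (default [probe_set()] plus the interneuron
#'   voltage).
#' @return List: `recording` (with probe `in_v` for the interneuron),
#'   `events` (data frame: cell, event, time).
#' @export
run_ffi_trial <- function(circuit, in_active = TRUE, t0 = 10, duration = 50,
                          probes = NULL) {
  stopifnot(inherits(circuit, "ffi_circuit"))
  model <- circuit$model
  if (is.null(probes)) probes <- probe_set()
  probes$in_v <- list(site = NULL, qty = "V")   # interneuron probe

  drive <- make_distributed_excitation(circuit$ex_pc_total_nS, onset = t0)
  proto <- do.call(protocol, drive)
  stim <- .build_stim(model, proto)
  # the IN->PC synapse starts with no events; the integrator appends the
  # event when the interneuron spikes
  out_idx <- length(stim$synapses)
  stim$synapses[[out_idx + 1]] <-
    list(seg = .seg_index(model, circuit$in_site) - 1L, type = 2L,
         tau_r = 0.5, tau_d = 5, gmax_uS = circuit$in_gmax_nS * 1e-3,
         erev = -73, onsets = numeric(0))
  inp <- circuit$interneuron
  stim$interneuron <- list(
    active = isTRUE(in_active), area_cm2 = inp$area_cm2, cm = inp$cm,
    gna_dens = inp$gna_dens, gk_dens = inp$gk_dens, gl_dens = inp$gl_dens,
    el = inp$el, ena = inp$ena, ek = inp$ek, phi = inp$phi,
    a_scale = inp$a_scale, b_scale = inp$b_scale, thresh = inp$thresh,
    delay = circuit$delay_ms,
    drive = list(tau_r = 0.5, tau_d = 2,
                 gmax_uS = circuit$ex_in_gmax_nS * 1e-3, erev = 0,
                 onsets = t0),
    out_syn_index = out_idx)

  spec <- simulation_spec(duration = duration, probes = probes)
  seg0 <- integer(length(probes)); qty <- integer(length(probes))
  for (j in seq_along(probes)) {
    p <- probes[[j]]
    if (is.null(p$site)) { seg0[j] <- -2L; qty[j] <- 0L }
    else { seg0[j] <- .seg_index(model, p$site) - 1L; qty[j] <- .qty_code(p$qty) }
  }
  st <- .settled_state(model, spec$dt, spec$settle, spec$v_init)
  res <- .engine_run(model$cpp, stim,
                     list(dt = spec$dt, duration = spec$duration,
                          v_init = spec$v_init, probe_seg = seg0,
                          probe_qty = qty),
                     st)
  series <- stats::setNames(
    lapply(seq_along(probes), function(j) res$series[, j]), names(probes))
  rec <- structure(list(time = res$time, series = series,
                        rest = vapply(series, function(x) x[1], numeric(1)),
                        probes = probes, spec = spec, protocol = proto,
                        in_spike_time = res$in_spike_time),
                   class = "recording")
  ev <- data.frame(cell = "EX", event = "spike", time = t0)
  if (!is.null(res$in_spike_time) && is.finite(res$in_spike_time)) {
    ev <- rbind(ev,
                data.frame(cell = "IN", event = "spike",
                           time = res$in_spike_time),
                if (isTRUE(in_active))
                  data.frame(cell = "IN", event = "ipsp_onset",
                             time = res$in_spike_time + circuit$delay_ms))
  }
  pc_spk <- detect_somatic_spikes(rec$series$soma, rec$time, rec$rest[["soma"]])
  if (length(pc_spk))
    ev <- rbind(ev, data.frame(cell = "PC", event = "spike", time = pc_spk))
  list(recording = rec, events = ev)
}

#' Effective excitation-to-inhibition delay of the circuit
#'
#' Onset of the IN->PC conductance at the pyramidal cell minus the onset of
#' the excitatory drive: the lumped feedforward delay (interneuron
#' integration + spike generation + dead time).  Invariant to `t0`.
#'
#' @param trial Result of [run_ffi_trial()] with the interneuron active.
#' @return Delay in ms.
#' @export
effective_delay <- function(trial) {
  ev <- trial$events
  ipsp <- ev$time[ev$event == "ipsp_onset"]
  if (!length(ipsp)) stop("interneuron did not spike (or was silenced)")
  ipsp - ev$time[ev$cell == "EX"][1]
}

#' Compare interneuron variants at a given inhibition site
#'
#' Runs the FFI trial with the fast and the slow interneuron variant and
#' classifies the outcome: at a proximal site the bAP class at the oblique
#' probe (only a short-latency interneuron meets the ~1 ms window); at a
#' distal site the calcium-spike ratio during BAC-like drive (both variants
#' are timely, since the calcium window is several ms wide).
#'
#' @param model Pyramidal `pyr_model`.
#' @param site_um_from_soma 90 (proximal) or 460 (distal), um on the apical
#'   path.
#' @param in_gmax_nS Inhibitory strength used for both variants.
#' @param distal_g_nS Distal pairing conductance used at the distal site to
#'   evoke the calcium spike.
#' @param t0 Source event time.
#' @return Data frame: variant, in_spike_ms, delay_ms, outcome,
#'   norm_bap/ca_ratio.
#' @export
interneuron_comparison <- function(model, site_um_from_soma = 90,
                                   in_gmax_nS = 50, distal_g_nS = 8,
                                   t0 = 10) {
  proximal <- site_um_from_soma < 300
  extra <- NULL
  if (!proximal) {
    # pair the drive with the distal synapse so a calcium spike is at stake;
    # align the distal event with the expected bAP arrival
    extra <- exp2_synapse(site_um(530, "apical"), 0.5, 2, distal_g_nS, 0,
                          onsets = t0 + 4)
  }
  run1 <- function(variant, active) {
    circ <- ffi_circuit(model, interneuron_model(variant),
                        in_site = site_um(site_um_from_soma, "apical"),
                        in_gmax_nS = in_gmax_nS)
    tr <- run_ffi_trial(circ, in_active = active, t0 = t0, duration = 60)
    if (!is.null(extra)) {
      # rerun with the distal pairing included
      circ2 <- circ
      tr <- .ffi_with_extra(circ2, extra, active, t0)
    }
    tr
  }
  rows <- lapply(c("fast", "slow"), function(vv) {
    ctrl <- run1(vv, FALSE)
    test <- run1(vv, TRUE)
    dly <- tryCatch(effective_delay(test), error = function(e) NA_real_)
    if (proximal) {
      cls <- classify_outcome(test$recording, ctrl$recording, "oblique370")
      data.frame(variant = vv,
                 in_spike_ms = test$events$time[test$events$cell == "IN" &
                                                  test$events$event == "spike"][1] - t0,
                 delay_ms = dly, outcome = cls,
                 measure = normalized_bap(test$recording, ctrl$recording,
                                          "oblique370"))
    } else {
      ratio <- calcium_spike_magnitude(test$recording, ctrl$recording)
      data.frame(variant = vv,
                 in_spike_ms = test$events$time[test$events$cell == "IN" &
                                                  test$events$event == "spike"][1] - t0,
                 delay_ms = dly,
                 outcome = if (ratio < 0.5) "CALCIUM_CANCELED" else "CALCIUM_INTACT",
                 measure = ratio)
    }
  })
  do.call(rbind, rows)
}

# FFI trial with an additional pyramidal synapse (distal pairing)
.ffi_with_extra <- function(circuit, extra, in_active, t0) {
  model <- circuit$model
  probes <- probe_set()
  probes$in_v <- list(site = NULL, qty = "V")
  drive <- c(make_distributed_excitation(circuit$ex_pc_total_nS, onset = t0),
             list(extra))
  proto <- do.call(protocol, drive)
  stim <- .build_stim(model, proto)
  out_idx <- length(stim$synapses)
  stim$synapses[[out_idx + 1]] <-
    list(seg = .seg_index(model, circuit$in_site) - 1L, type = 2L,
         tau_r = 0.5, tau_d = 5, gmax_uS = circuit$in_gmax_nS * 1e-3,
         erev = -73, onsets = numeric(0))
  inp <- circuit$interneuron
  stim$interneuron <- list(
    active = isTRUE(in_active), area_cm2 = inp$area_cm2, cm = inp$cm,
    gna_dens = inp$gna_dens, gk_dens = inp$gk_dens, gl_dens = inp$gl_dens,
    el = inp$el, ena = inp$ena, ek = inp$ek, phi = inp$phi,
    a_scale = inp$a_scale, b_scale = inp$b_scale, thresh = inp$thresh,
    delay = circuit$delay_ms,
    drive = list(tau_r = 0.5, tau_d = 2,
                 gmax_uS = circuit$ex_in_gmax_nS * 1e-3, erev = 0,
                 onsets = t0),
    out_syn_index = out_idx)
  spec <- simulation_spec(duration = 70, probes = probes)
  seg0 <- integer(length(probes)); qty <- integer(length(probes))
  for (j in seq_along(probes)) {
    p <- probes[[j]]
    if (is.null(p$site)) { seg0[j] <- -2L; qty[j] <- 0L }
    else { seg0[j] <- .seg_index(model, p$site) - 1L; qty[j] <- .qty_code(p$qty) }
  }
  st <- .settled_state(model, spec$dt, spec$settle, spec$v_init)
  res <- .engine_run(model$cpp, stim,
                     list(dt = spec$dt, duration = spec$duration,
                          v_init = spec$v_init, probe_seg = seg0,
                          probe_qty = qty),
                     st)
  series <- stats::setNames(
    lapply(seq_along(probes), function(j) res$series[, j]), names(probes))
  rec <- structure(list(time = res$time, series = series,
                        rest = vapply(series, function(x) x[1], numeric(1)),
                        probes = probes, spec = spec, protocol = proto,
                        in_spike_time = res$in_spike_time),
                   class = "recording")
  ev <- data.frame(cell = "EX", event = "spike", time = t0)
  if (!is.null(res$in_spike_time) && is.finite(res$in_spike_time)) {
    ev <- rbind(ev,
                data.frame(cell = "IN", event = "spike", time = res$in_spike_time),
                if (isTRUE(in_active))
                  data.frame(cell = "IN", event = "ipsp_onset",
                             time = res$in_spike_time + circuit$delay_ms))
  }
  list(recording = rec, events = ev)
}
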