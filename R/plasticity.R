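# Additive spike-timing-dependent plasticity (STDP), the 100-pairing / 1 Hz
# pairing protocol, and learning-window construction for basal, oblique and
# distal (apical tuft) synapses, with and without inhibition.
#
# The postsynaptic coincidence signal is site-specific: basal and oblique
# synapses detect the local depolarization of the bAP (voltage threshold
# -20 mV at the synapse), while the distal synapse detects the calcium spike
# (calcium-pool threshold 0.5 mM), reflecting the assumption that the calcium
# spike governs distal plasticity.

#' Additive STDP rule parameters
#'
#' Potentiation factor A+ = 0.001 and depression factor A- = 0.00106 (both
#' dimensionless fractions of the weight bound), time constants 20 ms, hard
#' weight bounds 0 and 1e-4 uS.
#'
#' @param a_plus,a_minus Potentiation/depression factors.
#' @param tau_plus,tau_minus Window time constants, ms.
#' @param w_min,w_max Hard weight bounds, uS.
#' @return An `stdp_rule` object.
#' @export
stdp_rule <- function(a_plus = 0.001, a_minus = 0.00106,
                      tau_plus = 20, tau_minus = 20,
                      w_min = 0, w_max = 1e-4) {
  stopifnot(a_plus > 0, a_minus > 0, tau_plus > 0, tau_minus > 0,
            w_min < w_max)
  structure(list(a_plus = a_plus, a_minus = a_minus, tau_plus = tau_plus,
                 tau_minus = tau_minus, w_min = w_min, w_max = w_max),
            class = "stdp_rule")
}

#' STDP weight change for a single pre/post pair
#'
#' For the pairing interval `dt = t_post - t_pre`:
#' `-A- * exp(dt / tau-)` for `dt <= 0` and `A+ * exp(-dt / tau+)` for
#' `dt > 0`, expressed as a fraction of the weight bound `w_max` (the rule is
#' additive: the step does not depend on the current weight).
#'
#' @param dt_ms Pairing interval(s) `t_post - t_pre`, ms (vectorized).
#' @param rule An [stdp_rule()].
#' @return Weight change in uS (fraction times `w_max`).
#' @examples
#' stdp_delta(0)    # -A- * w_max
#' stdp_delta(20)   # A+ * exp(-1) * w_max
#' @export
stdp_delta <- function(dt_ms, rule = stdp_rule()) {
  ifelse(dt_ms <= 0,
         -rule$a_minus * exp(dt_ms / rule$tau_minus),
         rule$a_plus * exp(-dt_ms / rule$tau_plus)) * rule$w_max
}

#' Plastic synapse definitions of the pairing protocol
#'
#' Basal (75 um, middle of the main shaft), oblique (250 um, middle of the
#' oblique dendrite) and distal (530 um, apical tuft) plastic synapses.  All
#' have a single-exponential conductance (tau 3 ms, reversal 0 mV).  The tuft
#' synapse carries 8 nS, the conductance required to trigger a calcium spike
#' when paired with a bAP; basal and oblique synapses start at a negligible
#' 0.001 nS.  Post events are detected in voltage mode (-20 mV at the
#' synapse) for basal/oblique and in calcium mode (0.5 mM) for the tuft.
#'
#' @param which One of `"basal"`, `"oblique"`, `"distal"`.
#' @return List describing the synapse: `site`, `gmax_nS`, `detector`,
#'   `threshold`.
#' @export
plastic_synapse <- function(which = c("basal", "oblique", "distal")) {
  which <- match.arg(which)
  switch(which,
         basal = list(name = "basal", site = site_um(75, "basal"),
                      gmax_nS = 0.001, detector = "voltage", threshold = -20),
         oblique = list(name = "oblique", site = site("oblique", 0.5),
                        gmax_nS = 0.001, detector = "voltage", threshold = -20),
         distal = list(name = "distal", site = site_um(530, "apical"),
                       gmax_nS = 8, detector = "calcium", threshold = 0.5))
}

# post-event times in one trial: upward crossings of the detector threshold
# at the synapse, separated by >= 2 ms (burst spikes count individually)
.post_events <- function(rec, probe, threshold, refractory = 2) {
  x <- rec$series[[probe]]
  up <- which(x[-1] >= threshold & x[-length(x)] < threshold) + 1L
  if (!length(up)) return(numeric(0))
  t <- rec$time[up]
  keep <- t[1]
  for (v in t[-1]) if (v - keep[length(keep)] >= refractory) keep <- c(keep, v)
  keep
}

# simulate one pairing trial; returns the per-pairing weight change (uS)
.pairing_trial <- function(model, syn, t_pre, t0, inhibition, rule,
                           duration = 80) {
  probes <- list(soma = list(site = site("soma", 0.5), qty = "V"))
  probes$syn <- list(site = syn$site,
                     qty = if (syn$detector == "calcium") "Ca" else "V")
  ev <- list(step_current(onset = t0),
             exp_synapse(syn$site, tau = 3, gmax_nS = syn$gmax_nS,
                         e_rev = 0, onsets = t_pre))
  if (!is.null(inhibition)) {
    if (inherits(inhibition, "syn_event")) inhibition <- list(inhibition)
    ev <- c(ev, inhibition)
  }
  rec <- simulate_protocol(model, do.call(protocol, ev),
                           simulation_spec(duration = duration,
                                           probes = probes))
  post <- .post_events(rec, "syn", syn$threshold)
  if (!length(post)) return(0)
  sum(stdp_delta(post - t_pre, rule))
}

#' Run the STDP pairing protocol at one pairing interval
#'
#' A somatic step current (0.3 nA, 2 ms) is paired `n_pairings` times at
#' `rate_hz` with activation of the plastic synapse.  The nominal pairing
#' interval `dt_ms` schedules the presynaptic event `dt_ms` before the
#' reference postsynaptic event time of the uninhibited protocol, and the
#' weight update uses the measured post-event times of the trial.  At 1 Hz
#' all state variables relax between pairings, so the trial is simulated once
#' from the settled rest state and the additive update (with hard bounds) is
#' iterated over the pairings.
#'
#' @param model A `pyr_model`.
#' @param syn A [plastic_synapse()] (or its name).
#' @param dt_ms Nominal pairing interval, ms (positive: pre before post).
#' @param inhibition Optional `syn_event` (or list) added to every trial;
#'   onset times are absolute trial times.
#' @param n_pairings Number of pairings (default 100).
#' @param rate_hz Pairing rate; with independent trials it only fixes the
#'   protocol duration (default 1 Hz).
#' @param rule An [stdp_rule()].
#' @param w_init Initial weight, uS (default: the synapse's initial
#'   conductance).
#' @param t0 Somatic stimulus onset within a trial, ms.
#' @return List: `dw` (accumulated weight change, uS), `w_final`,
#'   `dw_pairing` (per-pairing change before clipping), `n_post`.
#' @export
run_pairing_protocol <- function(model, syn, dt_ms, inhibition = NULL,
                                 n_pairings = 100, rate_hz = 1,
                                 rule = stdp_rule(), w_init = NULL, t0 = 20) {
  if (is.character(syn)) syn <- plastic_synapse(syn)
  # the tracked plastic weight starts small (0.001 nS); for the tuft synapse
  # it is separate from the 8 nS drive conductance that evokes the calcium
  # spike during the pairing
  if (is.null(w_init)) w_init <- min(max(1e-6, rule$w_min), rule$w_max)
  t_ref <- .post_reference(model, syn, t0)
  t_pre <- t_ref - dt_ms
  # events must lie inside the trial window
  dur <- max(80, t_pre + 40)
  dwp <- .pairing_trial(model, syn, t_pre, t0, inhibition, rule, duration = dur)
  w <- w_init
  for (i in seq_len(n_pairings)) w <- min(max(w + dwp, rule$w_min), rule$w_max)
  list(dw = w - w_init, w_final = w, dw_pairing = dwp)
}

# reference post-event time of the uninhibited pairing (cached on the model):
# the bAP arrival (voltage mode) or expected calcium-event time (calcium
# mode), measured with the plastic synapse at a negligible weight so the
# reference does not depend on dt
.post_reference <- function(model, syn, t0) {
  key <- sprintf("postref_%s_t0%g", syn$name, t0)
  val <- model$cache[[key]]
  if (!is.null(val)) return(val)
  probes <- list(soma = list(site = site("soma", 0.5), qty = "V"),
                 syn = list(site = syn$site, qty = "V"))
  rec <- simulate_protocol(model, protocol(step_current(onset = t0)),
                           simulation_spec(duration = t0 + 30, probes = probes))
  post <- .post_events(rec, "syn", -20)
  val <- if (length(post)) post[1] else {
    # no local -20 mV crossing (strongly attenuated site): use the somatic
    # spike time plus the voltage peak delay at the synapse
    spk <- detect_somatic_spikes(rec$series$soma, rec$time, rec$rest[["soma"]])
    if (length(spk)) rec$time[which.max(rec$series$syn)] else t0 + 2.5
  }
  model$cache[[key]] <- val
  val
}

#' Learning window over a grid of pairing intervals
#'
#' Runs [run_pairing_protocol()] for every `dt_ms` in the grid and normalizes
#' the accumulated change to the maximum absolute change of the uninhibited
#' window of the same synapse (a flat inhibited window is reported as zeros
#' with the uninhibited normalization constant).
#'
#' @inheritParams run_pairing_protocol
#' @param dt_grid Pairing intervals, ms (default 9 points spanning +-20 ms).
#' @param norm Normalization constant, uS; if `NULL` and `inhibition` is
#'   given, the uninhibited window is computed first.
#' @return Data frame: `dt_ms`, `dw_uS`, `dw_norm`, `site`, `condition`.
#' @export
learning_window <- function(model, syn, dt_grid = seq(-20, 20, by = 5),
                            inhibition = NULL, norm = NULL,
                            n_pairings = 100, rule = stdp_rule(), t0 = 20) {
  if (is.character(syn)) syn <- plastic_synapse(syn)
  dw <- vapply(dt_grid, function(d)
    run_pairing_protocol(model, syn, d, inhibition = inhibition,
                         n_pairings = n_pairings, rule = rule, t0 = t0)$dw,
    numeric(1))
  if (is.null(norm)) {
    if (is.null(inhibition)) norm <- max(abs(dw))
    else {
      dw0 <- vapply(dt_grid, function(d)
        run_pairing_protocol(model, syn, d, inhibition = NULL,
                             n_pairings = n_pairings, rule = rule, t0 = t0)$dw,
        numeric(1))
      norm <- max(abs(dw0))
    }
  }
  data.frame(dt_ms = dt_grid, dw_uS = dw,
             dw_norm = if (norm > 0) dw / norm else dw * 0,
             site = syn$name,
             condition = if (is.null(inhibition)) "control" else "inhibited")
}

#' Distal calcium signal as a function of the pairing interval
#'
#' For each pairing interval of the BAC protocol (somatic step paired with
#' the 8 nS distal synapse), reports the time integral and the peak of the
#' distal calcium concentration.  Over a +-20 ms grid the distribution of
#' integrals is bimodal: coincident pairings ignite the calcium spike (high
#' mode), non-coincident ones do not (low mode); with proximal or distal
#' inhibition every pairing falls in the low mode.
#'
#' @inheritParams learning_window
#' @param dt_grid Pairing intervals, ms.
#' @param distal_g_nS Conductance of the distal synapse (0 disables pairing).
#' @return Data frame: `dt_ms`, `ca_integral` (mM ms), `ca_peak` (mM).
#' @export
distal_calcium_scan <- function(model, dt_grid = seq(-20, 20, by = 5),
                                inhibition = NULL, distal_g_nS = 8, t0 = 20) {
  syn <- plastic_synapse("distal")
  syn$gmax_nS <- distal_g_nS
  t_ref <- .post_reference(model, syn, t0)
  probes <- list(soma = list(site = site("soma", 0.5), qty = "V"),
                 ca = list(site = site_um(650, "apical"), qty = "Ca"))
  rows <- lapply(dt_grid, function(d) {
    t_pre <- t_ref - d
    ev <- list(step_current(onset = t0))
    if (distal_g_nS > 0)
      ev <- c(ev, list(exp_synapse(syn$site, tau = 3, gmax_nS = distal_g_nS,
                                   e_rev = 0, onsets = t_pre)))
    if (!is.null(inhibition)) {
      inh <- if (inherits(inhibition, "syn_event")) list(inhibition) else inhibition
      ev <- c(ev, inh)
    }
    dur <- max(100, t_pre + 60)
    rec <- simulate_protocol(model, do.call(protocol, ev),
                             simulation_spec(duration = dur, probes = probes))
    dt_samp <- rec$time[2] - rec$time[1]
    data.frame(dt_ms = d,
               ca_integral = sum(rec$series$ca - rec$series$ca[1]) * dt_samp,
               ca_peak = max(rec$series$ca))
  })
  do.call(rbind, rows)
}
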