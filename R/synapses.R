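# Synthetic input generation: synapse conductance events, current steps, and
# the stimulation protocols used throughout the study.  Conductance synapses
# are peak-normalized: the maximum of a single event equals g_max.

#' Double-exponential conductance synapse specification
#'
#' @param site A `site_address`.
#' @param tau_r,tau_d Rise and decay time constants, ms (`tau_r < tau_d`).
#' @param gmax_nS Peak conductance of a single event, nS.
#' @param e_rev Reversal potential, mV.
#' @param onsets Event onset times, ms.
#' @return An event spec usable in [protocol()].
#' @export
exp2_synapse <- function(site, tau_r, tau_d, gmax_nS, e_rev, onsets) {
  if (!(tau_r > 0 && tau_r < tau_d)) stop("require 0 < tau_r < tau_d")
  if (gmax_nS < 0) stop("gmax must be >= 0")
  structure(list(site = site, type = 2L, tau_r = tau_r, tau_d = tau_d,
                 gmax_nS = gmax_nS, e_rev = e_rev, onsets = sort(onsets)),
            class = "syn_event")
}

#' Single-exponential conductance synapse specification
#'
#' @inheritParams exp2_synapse
#' @param tau Decay time constant, ms.
#' @export
exp_synapse <- function(site, tau = 3, gmax_nS, e_rev = 0, onsets) {
  if (tau <= 0) stop("tau must be > 0")
  if (gmax_nS < 0) stop("gmax must be >= 0")
  structure(list(site = site, type = 1L, tau_r = tau, tau_d = tau,
                 gmax_nS = gmax_nS, e_rev = e_rev, onsets = sort(onsets)),
            class = "syn_event")
}

#' Shunting (GABA-A like) inhibitory synapse
#'
#' Standard inhibition used throughout: double-exponential conductance with
#' rise 0.5 ms, decay 5 ms, reversal -73 mV (at rest it shunts rather than
#' hyperpolarizes).
#'
#' @inheritParams exp2_synapse
#' @export
inhibitory_synapse <- function(site, gmax_nS, onsets,
                               tau_r = 0.5, tau_d = 5, e_rev = -73) {
  exp2_synapse(site, tau_r, tau_d, gmax_nS, e_rev, onsets)
}

#' Somatic step current specification
#'
#' @param site Injection site (default soma centre).
#' @param amp_nA Amplitude, nA (default 0.3).
#' @param dur_ms Duration, ms (default 2).
#' @param onset Onset time, ms.
#' @export
step_current <- function(site = NULL, amp_nA = 0.3,
                         dur_ms = 2, onset = 0) {
  if (is.null(site)) site <- dendrogate::site("soma", 0.5)
  if (dur_ms <= 0) stop("duration must be > 0")
  structure(list(site = site, amp_nA = amp_nA, dur_ms = dur_ms,
                 onset = onset), class = "step_event")
}

#' Bundle stimulus events into a protocol
#'
#' @param ... `syn_event` / `step_event` objects (or lists of them).
#' @param seed Integer seed recorded with the protocol (only jittered
#'   protocols are stochastic; the seed is consumed at generation time).
#' @return A `stim_protocol`.
#' @export
protocol <- function(..., seed = NULL) {
  ev <- list(...)
  flat <- list()
  for (e in ev) {
    if (inherits(e, c("syn_event", "step_event"))) flat[[length(flat) + 1]] <- e
    else if (is.list(e)) for (x in e) {
      stopifnot(inherits(x, c("syn_event", "step_event")))
      flat[[length(flat) + 1]] <- x
    }
    else stop("protocol() accepts syn_event / step_event objects")
  }
  structure(list(events = flat, seed = seed), class = "stim_protocol")
}

#' Evaluate the conductance waveform of a synapse spec
#'
#' Closed form of the peak-normalized double (or single) exponential summed
#' over all onsets; zero before each onset.
#'
#' @param t Times, ms.
#' @param spec A `syn_event`.
#' @return Conductance in uS at each `t`.
#' @examples
#' s <- exp2_synapse(site("trunk_prox", 0.9), 0.5, 5, 10, -73, onsets = 0)
#' max(exp2_waveform(seq(0, 30, 0.001), s)) # ~0.010 uS = 10 nS
#' @export
exp2_waveform <- function(t, spec) {
  stopifnot(inherits(spec, "syn_event"))
  g <- numeric(length(t))
  gmax <- spec$gmax_nS * 1e-3 # uS
  if (spec$type == 2L) {
    tr <- spec$tau_r; td <- spec$tau_d
    tp <- tr * td / (td - tr) * log(td / tr)
    f <- 1 / (exp(-tp / td) - exp(-tp / tr))
    for (on in spec$onsets) {
      u <- t - on
      g <- g + ifelse(u >= 0, gmax * f * (exp(-u / td) - exp(-u / tr)), 0)
    }
  } else {
    for (on in spec$onsets) {
      u <- t - on
      g <- g + ifelse(u >= 0, gmax * exp(-u / spec$tau_d), 0)
    }
  }
  g
}

#' Pairing protocol for BAC firing
#'
#' Somatic step current (0.3 nA, 2 ms) at `t0`, followed after `dt_ms` by a
#' distal excitatory event (double exponential, rise 0.5 ms / decay 2 ms,
#' reversal 0 mV) at 530 um on the apical path.  With the default 8 nS distal
#' conductance this elicits a dendritic calcium spike and a burst of two
#' somatic action potentials; 14 nS alone (no somatic step) elicits a calcium
#' spike without a preceding bAP.
#'
#' @param dt_ms Interval between somatic and dendritic stimulation, ms.
#' @param distal_g_nS Peak conductance of the distal synapse.
#' @param t0 Somatic stimulus onset, ms.
#' @param somatic Include the somatic step (set `FALSE` for distal-only).
#' @param distal_um Location of the distal synapse on the apical path.
#' @return A `stim_protocol`.
#' @export
make_bac_pairing <- function(dt_ms = 5, distal_g_nS = 8, t0 = 10,
                             somatic = TRUE, distal_um = 530) {
  ev <- list()
  if (somatic) ev[[1]] <- step_current(onset = t0)
  if (distal_g_nS > 0)
    ev[[length(ev) + 1]] <- exp2_synapse(site_um(distal_um, "apical"),
                                         0.5, 2, distal_g_nS, 0,
                                         onsets = t0 + dt_ms)
  do.call(protocol, ev)
}

#' Distributed excitation along the apical trunk
#'
#' `n` synchronous excitatory synapses (rise 0.5 ms / decay 2 ms, reversal
#' 0 mV) at equally spaced positions spanning 140-420 um on the apical trunk
#' (endpoints inclusive; `n = 1` degenerates to the midpoint), sharing
#' `total_g_nS` equally.  Represents input arriving from putative oblique
#' dendrites.
#'
#' @param total_g_nS Summed peak conductance, nS.
#' @param n Number of synapses.
#' @param onset Common onset time, ms.
#' @param span_um Endpoints of the spatial span.
#' @return List of `syn_event`s.
#' @export
make_distributed_excitation <- function(total_g_nS = 20, n = 8, onset = 0,
                                        span_um = c(140, 420)) {
  if (n < 1) stop("n must be >= 1")
  pos <- if (n == 1) mean(span_um) else seq(span_um[1], span_um[2], length.out = n)
  lapply(pos, function(p)
    exp2_synapse(site_um(p, "apical"), 0.5, 2, total_g_nS / n, 0,
                 onsets = onset))
}

#' Repetitive inhibitory input (pulse train)
#'
#' One shunting synapse activated `n_pulses` times at `freq_hz`, e.g. the
#' four-pulse 75 Hz basal train that suppresses the burst of bAPs during BAC
#' firing.
#'
#' @param n_pulses Number of activations (>= 1).
#' @param freq_hz Train frequency, Hz (> 0).
#' @param gmax_nS Peak conductance per activation, nS.
#' @param site Target `site_address`.
#' @param onset First activation time, ms.
#' @return A `syn_event` with multiple onsets.
#' @export
make_inhibitory_train <- function(n_pulses, freq_hz, gmax_nS, site, onset = 0) {
  if (n_pulses < 1) stop("n_pulses must be >= 1")
  if (freq_hz <= 0) stop("freq must be > 0")
  inhibitory_synapse(site, gmax_nS,
                     onsets = onset + (seq_len(n_pulses) - 1) * 1000 / freq_hz)
}

#' Spatio-temporally jittered inhibitory synapses
#'
#' `n_syn` shunting synapses of `gmax_nS` each, positions drawn from a
#' Gaussian centred at 90 um on the apical trunk (truncated to the trunk) and
#' onsets from a Gaussian centred 2 ms after the stimulus onset.
#' Deterministic for a given seed.
#'
#' @param n_syn Number of synapses.
#' @param sigma_space_um Spatial standard deviation, um (>= 0).
#' @param sigma_time_ms Temporal standard deviation, ms (>= 0).
#' @param seed Integer seed.
#' @param stim_onset Stimulus onset the temporal centre refers to, ms.
#' @param center_um Spatial centre, um from the soma.
#' @param gmax_nS Conductance per synapse, nS.
#' @param trunk_range_um Truncation interval (the apical trunk).
#' @return List of `syn_event`s.
#' @export
make_jittered_inhibition <- function(n_syn, sigma_space_um, sigma_time_ms,
                                     seed, stim_onset = 10, center_um = 90,
                                     gmax_nS = 1,
                                     trunk_range_um = c(0, 500)) {
  if (sigma_space_um < 0 || sigma_time_ms < 0) stop("sigma must be >= 0")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  pos <- stats::rnorm(n_syn, center_um, sigma_space_um)
  # truncate by resampling out-of-trunk draws
  bad <- pos < trunk_range_um[1] | pos > trunk_range_um[2]
  while (any(bad)) {
    pos[bad] <- stats::rnorm(sum(bad), center_um, sigma_space_um)
    bad <- pos < trunk_range_um[1] | pos > trunk_range_um[2]
  }
  ons <- stats::rnorm(n_syn, stim_onset + 2, sigma_time_ms)
  lapply(seq_len(n_syn), function(i)
    inhibitory_synapse(site_um(pos[i], "apical"), gmax_nS, onsets = ons[i]))
}

#' Periodic suprathreshold somatic drive
#'
#' Repeated somatic step currents (0.3 nA, 2 ms each) at a fixed rate for the
#' full duration; used to scan the critical somatic firing frequency above
#' which a distal calcium spike is triggered.
#'
#' @param freq_hz Stimulation frequency, Hz (> 0).
#' @param duration_ms Total drive duration, ms.
#' @param t0 Time of the first pulse, ms.
#' @param amp_nA,dur_ms Pulse amplitude and width.
#' @return A `stim_protocol`.
#' @export
make_frequency_drive <- function(freq_hz, duration_ms = 600, t0 = 0,
                                 amp_nA = 0.3, dur_ms = 2) {
  if (freq_hz <= 0) stop("freq must be > 0")
  n <- max(1L, floor(duration_ms * freq_hz / 1000))
  onsets <- t0 + (seq_len(n) - 1) * 1000 / freq_hz
  do.call(protocol, lapply(onsets, function(on)
    step_current(onset = on, amp_nA = amp_nA, dur_ms = dur_ms)))
}
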