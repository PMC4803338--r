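# Quantification of recordings: spike amplitude, somatic spike detection,
# bAP normalization, calcium-spike magnitude and the three-way gating
# classification used throughout the analysis.

#' Spike amplitude of a voltage trace
#'
#' Maximum voltage deviation from rest: a trace peaking at 10 mV from a rest
#' of -73 mV has an amplitude of 83 mV.
#'
#' @param trace Voltage series, mV.
#' @param v_rest Resting potential, mV.
#' @return Amplitude in mV.
#' @export
amplitude <- function(trace, v_rest) {
  if (!length(trace)) stop("empty trace")
  max(trace) - v_rest
}

#' Detect somatic spikes
#'
#' Upward crossings of `v_rest + threshold` (threshold 80 mV), with a
#' refractory separation of 2 ms between detections so a single spike is
#' never double-counted while burst spikes still register individually.
#'
#' @param trace Voltage series, mV.
#' @param time Time grid, ms (same length as `trace`).
#' @param v_rest Resting potential, mV.
#' @param threshold_mV Amplitude threshold above rest.
#' @param refractory_ms Minimal separation between detections.
#' @return Numeric vector of spike times (possibly empty).
#' @export
detect_somatic_spikes <- function(trace, time, v_rest, threshold_mV = 80,
                                  refractory_ms = 2) {
  th <- v_rest + threshold_mV
  up <- which(trace[-1] >= th & trace[-length(trace)] < th) + 1L
  if (!length(up)) return(numeric(0))
  t <- time[up]
  keep <- t[1]
  for (x in t[-1]) if (x - keep[length(keep)] >= refractory_ms) keep <- c(keep, x)
  keep
}

# amplitude of the first (non-inhibited) bAP in a control recording: the
# maximum deviation up to the second somatic spike (bursts contribute only
# their first event to the normalization reference)
.first_bap_amplitude <- function(control, probe) {
  soma_spikes <- detect_somatic_spikes(control$series$soma, control$time,
                                       control$rest[["soma"]])
  tr <- control$series[[probe]]
  if (length(soma_spikes) >= 2) {
    tr <- tr[control$time < soma_spikes[2]]
    if (!length(tr)) tr <- control$series[[probe]]
  }
  max(tr) - control$rest[[probe]]
}

#' Normalized bAP amplitude
#'
#' Amplitude of the (possibly inhibited) backpropagating action potential at
#' a dendritic probe, normalized to the amplitude of the first bAP in the
#' matching non-inhibited control recording.
#'
#' @param test,control `recording`s from the same protocol with and without
#'   inhibition.
#' @param probe Probe name (e.g. `"oblique370"`).
#' @return Ratio in `[0, ~1.1]`.
#' @export
normalized_bap <- function(test, control, probe) {
  ref <- .first_bap_amplitude(control, probe)
  if (ref <= 0) stop("zero control bAP amplitude at probe ", probe)
  (max(test$series[[probe]]) - test$rest[[probe]]) / ref
}

#' Calcium-spike magnitude ratio
#'
#' Integral of the (inward) calcium current at the tuft probe in the test
#' recording, normalized to the non-inhibited control.  The calcium current
#' disambiguates the calcium spike from the sodium components of the local
#' voltage.
#'
#' @param test,control `recording`s with a calcium-current probe.
#' @param probe Name of the calcium-current probe.
#' @return Ratio (1 = unaffected, ~0 = abolished).
#' @export
calcium_spike_magnitude <- function(test, control, probe = "tuft650_ica") {
  dt <- diff(test$time[1:2])
  int <- function(rec) sum(pmax(-rec$series[[probe]], 0)) * dt
  denom <- int(control)
  if (denom <= 0) stop("zero control calcium-current integral")
  int(test) / denom
}

#' Three-way gating classification of an inhibited trial
#'
#' `NO_SOMATIC_SPIKE` if the somatic trace has no spike;
#' `BAP_CANCELED_SPIKE_INTACT` if the soma spikes but the normalized bAP at
#' the dendritic probe falls below the classification threshold (the
#' all-or-none transition leaves an empty band around 0.5, so any mid-band
#' threshold is equivalent); otherwise `BAP_INTACT`.
#'
#' @inheritParams normalized_bap
#' @param threshold Normalized-amplitude cutoff (default 0.5).
#' @return Character scalar, one of the three outcome classes.
#' @export
classify_outcome <- function(test, control, probe = "oblique370",
                             threshold = 0.5) {
  spikes <- detect_somatic_spikes(test$series$soma, test$time,
                                  test$rest[["soma"]])
  if (!length(spikes)) return("NO_SOMATIC_SPIKE")
  nb <- normalized_bap(test, control, probe)
  if (nb < threshold) "BAP_CANCELED_SPIKE_INTACT" else "BAP_INTACT"
}

#' Split a set of values into two clusters at the largest gap
#'
#' Helper for the all-or-none analyses: orders the values, cuts at the widest
#' gap and reports both clusters and the gap width.  Used to verify
#' bimodality (an empty mid band) of normalized bAP amplitudes and calcium
#' integrals.
#'
#' @param x Numeric values.
#' @return List with `low`, `high` (the clusters), `gap` (width of the empty
#'   interval) and `cut` (its midpoint).
#' @export
split_bimodal <- function(x) {
  s <- sort(x)
  if (length(s) < 2) stop("need at least two values")
  d <- diff(s)
  i <- which.max(d)
  list(low = s[seq_len(i)], high = s[-seq_len(i)], gap = d[i],
       cut = (s[i] + s[i + 1]) / 2)
}
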