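# Scripted drivers for the figure-level scans: critical-frequency scan,
# critical-conductance bisection, timing/strength maps, compartment matrices,
# and a registry of named experiments with tidy-table output.

# standard control protocols per stimulation paradigm
.paradigm_protocol <- function(paradigm, t0, dt_pair = 0, distal_g = 8) {
  switch(paradigm,
         somatic_step = protocol(step_current(onset = t0)),
         dendritic_drive = do.call(protocol,
                                   make_distributed_excitation(onset = t0)),
         bac = make_bac_pairing(dt_pair, distal_g, t0 = t0),
         stop("unknown paradigm: ", paradigm))
}

#' Critical somatic firing frequency for distal calcium-spike initiation
#'
#' Drives the soma with periodic suprathreshold pulses for a fixed duration
#' at each frequency, accumulates the distal membrane-potential deviation
#' from rest over the run and normalizes by the value at the highest grid
#' frequency.  Below the critical frequency the cumulative signal grows
#' smoothly (saturating summation of bAP residues): its increments shrink
#' monotonically with frequency.  Calcium-spike ignition breaks that trend
#' with an abrupt extra increment; the critical frequency is the lowest grid
#' frequency whose increment exceeds `trend_ratio` times the preceding
#' increment (and an absolute floor).  A scan with no such break (e.g. with
#' the calcium zone disabled) is an error.
#'
#' @param model A `pyr_model`.
#' @param freqs Frequency grid, Hz (default 40-90 in 5 Hz steps).
#' @param duration_ms Drive duration per frequency (default 600).
#' @param trend_ratio Increment ratio that counts as abrupt (default 3).
#' @param min_jump Absolute floor for the ignition increment.
#' @return List: `critical_hz`, `table` (freq, cumulative, normalized).
#' @export
critical_frequency_scan <- function(model, freqs = seq(40, 90, by = 5),
                                    duration_ms = 600, trend_ratio = 3,
                                    min_jump = 0.02) {
  stopifnot(length(freqs) >= 3)
  cum <- vapply(freqs, function(f) {
    rec <- simulate_protocol(model, make_frequency_drive(f, duration_ms),
                             simulation_spec(duration = duration_ms))
    dt <- rec$time[2] - rec$time[1]
    sum(rec$series$tuft650 - rec$rest[["tuft650"]]) * dt
  }, numeric(1))
  nrm <- cum / cum[length(cum)]
  tab <- data.frame(freq_hz = freqs, cumulative = cum, normalized = nrm)
  jumps <- diff(nrm)
  hit <- which(jumps[-1] >= min_jump &
                 jumps[-1] >= trend_ratio * pmax(jumps[-length(jumps)], 1e-3))
  if (!length(hit))
    stop("no abrupt transition found on the frequency grid")
  list(critical_hz = freqs[min(hit) + 2], table = tab)
}

#' Critical inhibitory conductance by bisection
#'
#' Finds the minimal strength of a single shunting synapse (onset relative
#' to the somatic stimulus) that cancels the bAP at the oblique probe, to a
#' given resolution.  The all-or-none transition guarantees the bisection is
#' well posed: below the critical strength the normalized amplitude is ~1,
#' above it ~0-0.3.
#'
#' @param model A `pyr_model`.
#' @param location_um Inhibition site on the apical trunk, um from the soma.
#' @param onset_ms Inhibition onset relative to stimulation onset (default 2).
#' @param resolution_nS Bisection resolution (default 0.5).
#' @param bracket_nS Search bracket (default 0-200 nS).
#' @param probe Dendritic probe for the bAP (default oblique, 370 um).
#' @param t0 Stimulation onset, ms.
#' @return List: `critical_nS`, `n_evals`, plus the bracketing strengths.
#' @export
critical_conductance <- function(model, location_um = 90, onset_ms = 2,
                                 resolution_nS = 0.5,
                                 bracket_nS = c(0, 200),
                                 probe = "oblique370", t0 = 10) {
  spec <- simulation_spec(duration = t0 + 30)
  ctrl <- simulate_protocol(model, protocol(step_current(onset = t0)), spec)
  canceled <- function(g) {
    if (g <= 0) return(FALSE)
    p <- protocol(step_current(onset = t0),
                  inhibitory_synapse(site_um(location_um, "apical"), g,
                                     onsets = t0 + onset_ms))
    rec <- simulate_protocol(model, p, spec)
    normalized_bap(rec, ctrl, probe) < 0.5
  }
  lo <- bracket_nS[1]; hi <- bracket_nS[2]
  if (canceled(lo)) stop("lower bracket already cancels the bAP")
  if (!canceled(hi)) stop("no transition within [", lo, ", ", hi, "] nS")
  n <- 2L
  while (hi - lo > resolution_nS) {
    mid <- (lo + hi) / 2
    if (canceled(mid)) hi <- mid else lo <- mid
    n <- n + 1L
  }
  # the minimal canceling strength is the smallest strength seen to cancel
  list(critical_nS = hi, lower_nS = lo, upper_nS = hi, n_evals = n)
}

#' Timing/strength map of inhibitory gating
#'
#' Classifies the outcome of one inhibited trial per (strength, onset) grid
#' point under a stimulation paradigm, against the matching uninhibited
#' control: the three-way bAP class at a dendritic probe (`target = "bap"`)
#' or the normalized calcium-current integral at the tuft
#' (`target = "calcium"`).
#'
#' @param model A `pyr_model`.
#' @param location_um Inhibition site (apical path by default; use
#'   `path = "basal"` for basal inhibition).
#' @param paradigm `"somatic_step"`, `"dendritic_drive"` or `"bac"`.
#' @param target `"bap"` or `"calcium"`.
#' @param strengths_nS,onsets_ms Grid (onsets relative to stimulation onset).
#' @param probe bAP probe (default oblique, 370 um).
#' @param path Route for `location_um`.
#' @param dt_pair BAC pairing interval, ms.
#' @param t0 Stimulation onset, ms.
#' @return A `scan_result`: list with tidy `table` (strength_nS, onset_ms,
#'   class, norm_bap, ca_ratio) and the scan metadata.
#' @export
timing_strength_map <- function(model, location_um = 90,
                                paradigm = c("somatic_step",
                                             "dendritic_drive", "bac"),
                                target = c("bap", "calcium"),
                                strengths_nS = 50,
                                onsets_ms = seq(-2, 6, by = 0.25),
                                probe = "oblique370", path = "apical",
                                dt_pair = 0, t0 = 10) {
  paradigm <- match.arg(paradigm)
  target <- match.arg(target)
  dur <- if (paradigm == "bac") t0 + 70 else t0 + 30
  spec <- simulation_spec(duration = dur)
  base <- .paradigm_protocol(paradigm, t0, dt_pair)
  ctrl <- simulate_protocol(model, base, spec)
  rows <- list()
  for (g in strengths_nS) for (on in onsets_ms) {
    p <- do.call(protocol, c(base$events, list(
      inhibitory_synapse(site_um(location_um, path), g, onsets = t0 + on))))
    rec <- simulate_protocol(model, p, spec)
    cls <- classify_outcome(rec, ctrl, probe)
    nb <- if (cls == "NO_SOMATIC_SPIKE") NA_real_
          else normalized_bap(rec, ctrl, probe)
    car <- if (target == "calcium") calcium_spike_magnitude(rec, ctrl)
           else NA_real_
    if (target == "calcium" && cls != "NO_SOMATIC_SPIKE")
      cls <- if (car < 0.5) "CALCIUM_CANCELED" else "CALCIUM_INTACT"
    rows[[length(rows) + 1]] <-
      data.frame(strength_nS = g, onset_ms = on, location_um = location_um,
                 class = cls, norm_bap = nb, ca_ratio = car)
  }
  structure(list(table = do.call(rbind, rows), paradigm = paradigm,
                 target = target, probe = probe, t0 = t0,
                 onset_step = if (length(onsets_ms) > 1)
                   stats::median(diff(onsets_ms)) else NA_real_),
            class = "scan_result")
}

#' Onset-window width from a timing/strength map
#'
#' Extent along the onset axis of the "canceled" class
#' (`BAP_CANCELED_SPIKE_INTACT` for bAP targets, `CALCIUM_CANCELED` for
#' calcium targets) at one strength: the distance between the first and the
#' last canceled onset, plus nothing for a single point (width 0 means no
#' window at the grid resolution).
#'
#' @param map A `scan_result` from [timing_strength_map()].
#' @param strength_nS Strength row to measure (default: the only one).
#' @return Width in ms.
#' @export
window_width <- function(map, strength_nS = NULL) {
  tab <- map$table
  if (is.null(strength_nS)) strength_nS <- tab$strength_nS[1]
  cls <- if (map$target == "calcium") "CALCIUM_CANCELED"
         else "BAP_CANCELED_SPIKE_INTACT"
  on <- tab$onset_ms[tab$strength_nS == strength_nS & tab$class == cls]
  if (!length(on)) return(0)
  diff(range(on))
}

#' Compartment-by-compartment gating matrix
#'
#' Reproduces the signal/cancellation pattern across (inhibition condition x
#' recording site): somatic-step or BAC-firing stimulation; inhibition
#' conditions none / distal (460 um, 50 nS) / proximal (90 um, 50 nS) /
#' basal (100 um, 50 nS), plus, for the BAC paradigm, a basal four-pulse
#' 75 Hz train (70 nS).  A cell's local signal counts as canceled when the
#' normalized amplitude (or, for the tuft during BAC firing, the calcium
#' ratio) falls below 0.5.
#'
#' @param model A `pyr_model`.
#' @param paradigm `"somatic_step"` or `"bac"`.
#' @param t0 Stimulation onset, ms; inhibition onset is t0 + 1.5.
#' @return Data frame: condition, probe, measure, value, canceled.
#' @export
compartment_matrix <- function(model, paradigm = c("somatic_step", "bac"),
                               t0 = 10) {
  paradigm <- match.arg(paradigm)
  dur <- if (paradigm == "bac") t0 + 80 else t0 + 30
  spec <- simulation_spec(duration = dur)
  base <- .paradigm_protocol(paradigm, t0)
  ctrl <- simulate_protocol(model, base, spec)
  conds <- list(
    distal = inhibitory_synapse(site_um(460, "apical"), 50, onsets = t0 + 1.5),
    proximal = inhibitory_synapse(site_um(90, "apical"), 50, onsets = t0 + 1.5),
    basal = inhibitory_synapse(site_um(100, "basal"), 50, onsets = t0 + 1.5))
  if (paradigm == "bac")
    conds$basal_train <- make_inhibitory_train(4, 75, 70,
                                               site_um(100, "basal"),
                                               onset = t0 + 1.5)
  probes <- c("basal75", "oblique370", "tuft650")
  rows <- list()
  for (nm in names(conds)) {
    p <- do.call(protocol, c(base$events, list(conds[[nm]])))
    rec <- simulate_protocol(model, p, spec)
    for (pr in probes) {
      if (pr == "tuft650" && paradigm == "bac") {
        val <- calcium_spike_magnitude(rec, ctrl)
        meas <- "ca_ratio"
      } else {
        val <- normalized_bap(rec, ctrl, pr)
        meas <- "norm_bap"
      }
      rows[[length(rows) + 1]] <-
        data.frame(condition = nm, probe = pr, measure = meas,
                   value = val, canceled = val < 0.5)
    }
  }
  do.call(rbind, rows)
}

#' Known experiment identifiers
#' @return Character vector of ids accepted by [run_experiment()].
#' @export
experiment_ids <- function() {
  c("fig1f", "fig2", "fig3b", "fig3c", "fig4b", "fig6", "fig7",
    "s1", "s2", "s3", "s4", "s6")
}

#' Run a named figure-reproduction experiment
#'
#' Each id maps to one figure-level scan; results are returned as (and
#' optionally written to) tidy tables together with a JSON metadata record
#' sufficient to re-run the scan.  All scans are deterministic given the
#' seed.
#'
#' @param id One of [experiment_ids()].
#' @param model A `pyr_model` (default model if `NULL`).
#' @param out_dir Optional output directory for `<id>.csv` +
#'   `<id>_meta.json`.
#' @param seed Integer seed (only the jittered-inhibition experiment s1 is
#'   stochastic).
#' @param quick If `TRUE`, coarser grids (used by the test suite).
#' @return List with `table` (tidy data frame) and `summary` (named list of
#'   derived quantities).
#' @export
run_experiment <- function(id, model = NULL, out_dir = NULL, seed = 1,
                           quick = FALSE) {
  id <- match.arg(id, experiment_ids())
  if (is.null(model)) model <- build_neuron_model()
  t0 <- 10
  res <- switch(
    id,
    fig1f = {
      sc <- critical_frequency_scan(model,
                                    freqs = if (quick) seq(60, 90, 5)
                                            else seq(40, 90, 5))
      list(table = sc$table, summary = list(critical_hz = sc$critical_hz))
    },
    fig2 = {
      locs <- if (quick) c(30, 90) else c(30, 60, 90, 95)
      tabs <- lapply(locs, function(L) {
        sweep <- .strength_sweep(model, L, if (quick) seq(10, 120, 10)
                                          else seq(4, 120, 4), t0)
        sweep$location_um <- L
        sweep
      })
      tab <- do.call(rbind, tabs)
      crit <- vapply(locs, function(L) {
        s <- tab[tab$location_um == L, ]
        low <- s$strength_nS[s$norm_bap < 0.5]
        if (length(low)) min(low) else NA_real_
      }, numeric(1))
      list(table = tab,
           summary = list(critical_nS = stats::setNames(crit, locs)))
    },
    fig3b = {
      m <- timing_strength_map(model, 90, "somatic_step", "bap",
                               strengths_nS = if (quick) c(20, 50)
                                              else seq(10, 80, 10),
                               onsets_ms = seq(-2, 6,
                                               by = if (quick) 0.5 else 0.25))
      list(table = m$table,
           summary = list(width_50nS_ms = window_width(m, 50)))
    },
    fig3c = {
      m <- timing_strength_map(model, 90, "dendritic_drive", "bap",
                               strengths_nS = 50,
                               onsets_ms = seq(0, 6,
                                               by = if (quick) 0.5 else 0.25))
      list(table = m$table,
           summary = list(width_50nS_ms = window_width(m, 50)))
    },
    fig4b = {
      m <- timing_strength_map(model, 460, "bac", "calcium",
                               strengths_nS = 30,
                               onsets_ms = seq(-8, 12,
                                               by = if (quick) 1 else 0.5))
      list(table = m$table,
           summary = list(width_30nS_ms = window_width(m, 30)))
    },
    fig6 = {
      grid <- if (quick) seq(-20, 20, 10) else seq(-20, 20, 5)
      inh <- list(
        none = NULL,
        distal = inhibitory_synapse(site_um(460, "apical"), 50,
                                    onsets = 20 + 1.5),
        proximal = inhibitory_synapse(site_um(90, "apical"), 50,
                                      onsets = 20 + 1.5),
        basal = inhibitory_synapse(site_um(100, "basal"), 50,
                                   onsets = 20 + 1.5))
      tabs <- list()
      for (syn in c("basal", "oblique", "distal")) {
        w0 <- learning_window(model, syn, grid)
        w0$condition <- "control"
        tabs[[length(tabs) + 1]] <- w0
        cond <- switch(syn, basal = "basal", oblique = "proximal",
                       distal = "distal")
        wi <- learning_window(model, syn, grid, inhibition = inh[[cond]],
                              norm = max(abs(w0$dw_uS)))
        wi$condition <- cond
        tabs[[length(tabs) + 1]] <- wi
      }
      tab <- do.call(rbind, tabs)
      list(table = tab,
           summary = list(
             flat_inhibited = all(tab$dw_uS[tab$condition != "control"] == 0)))
    },
    fig7 = {
      circ <- ffi_circuit(model)
      off <- run_ffi_trial(circ, in_active = FALSE, t0 = t0)
      on <- run_ffi_trial(circ, in_active = TRUE, t0 = t0)
      tab <- rbind(cbind(paradigm = "in_silenced", off$events),
                   cbind(paradigm = "in_active", on$events))
      list(table = tab,
           summary = list(
             delay_ms = effective_delay(on),
             class_silenced = classify_outcome(off$recording, off$recording),
             class_active = classify_outcome(on$recording, off$recording)))
    },
    s1 = {
      sig <- if (quick) c(0, 20) else c(0, 10, 25, 50)
      ns <- if (quick) c(20, 30) else c(10, 20, 25, 30, 40)
      spec <- simulation_spec(duration = t0 + 30)
      ctrl <- simulate_protocol(model, protocol(step_current(onset = t0)),
                                spec)
      rows <- list()
      for (s in sig) for (n in ns) {
        jit <- make_jittered_inhibition(n, s, 0.5, seed = seed + n + s,
                                        stim_onset = t0)
        p <- do.call(protocol, c(list(step_current(onset = t0)), jit))
        rec <- simulate_protocol(model, p, spec)
        rows[[length(rows) + 1]] <-
          data.frame(sigma_um = s, n_syn = n,
                     norm_bap = normalized_bap(rec, ctrl, "oblique370"))
      }
      tab <- do.call(rbind, rows)
      list(table = tab,
           summary = list(all_or_none =
             !any(tab$norm_bap > 0.4 & tab$norm_bap < 0.6)))
    },
    s2 = {
      freqs <- if (quick) c(50, 75) else c(50, 75, 100, 125)
      np <- if (quick) c(1, 4) else 1:5
      base <- make_bac_pairing(0, 8, t0 = t0)
      spec <- simulation_spec(duration = t0 + 80)
      ctrl <- simulate_protocol(model, base, spec)
      rows <- list()
      for (f in freqs) for (n in np) {
        p <- do.call(protocol, c(base$events, list(
          make_inhibitory_train(n, f, 70, site_um(100, "basal"),
                                onset = t0 + 1.5))))
        rec <- simulate_protocol(model, p, spec)
        rows[[length(rows) + 1]] <-
          data.frame(freq_hz = f, n_pulses = n,
                     norm_bap_basal = normalized_bap(rec, ctrl, "basal75"))
      }
      list(table = do.call(rbind, rows), summary = list())
    },
    s3 = {
      m <- timing_strength_map(model, 460, "bac", "bap",
                               strengths_nS = 50,
                               onsets_ms = seq(-2, 6,
                                               by = if (quick) 0.5 else 0.25))
      list(table = m$table,
           summary = list(
             distal_cancels_oblique_bap =
               any(m$table$class == "BAP_CANCELED_SPIKE_INTACT")))
    },
    s4 = {
      locs <- if (quick) c(30, 90, 150) else c(30, 60, 90, 150)
      widths <- vapply(locs, function(L) {
        m <- timing_strength_map(model, L, "dendritic_drive", "bap",
                                 strengths_nS = 50,
                                 onsets_ms = seq(0, 6, by = 0.25))
        window_width(m, 50)
      }, numeric(1))
      list(table = data.frame(location_um = locs, width_ms = widths),
           summary = list(widths_ms = stats::setNames(widths, locs)))
    },
    s6 = {
      tab <- rbind(cbind(site_um = 90, interneuron_comparison(model, 90)),
                   cbind(site_um = 460,
                         interneuron_comparison(model, 460, in_gmax_nS = 30)))
      list(table = tab, summary = list())
    })
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(res$table, file.path(out_dir, paste0(id, ".csv")),
                     row.names = FALSE)
    meta <- list(id = id, seed = seed, quick = quick,
                 timestamp = format(Sys.time(), tz = "UTC"),
                 channel_params = attr(model$densities, "params"),
                 kinetics = model$kin,
                 summary = res$summary)
    jsonlite::write_json(meta, file.path(out_dir, paste0(id, "_meta.json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  res
}

# all-or-none strength sweep at one location (Fig 2B)
.strength_sweep <- function(model, location_um, strengths_nS, t0 = 10,
                            onset_ms = 2, probe = "oblique370") {
  spec <- simulation_spec(duration = t0 + 30)
  ctrl <- simulate_protocol(model, protocol(step_current(onset = t0)), spec)
  nb <- vapply(strengths_nS, function(g) {
    p <- protocol(step_current(onset = t0),
                  inhibitory_synapse(site_um(location_um, "apical"), g,
                                     onsets = t0 + onset_ms))
    normalized_bap(simulate_protocol(model, p, spec), ctrl, probe)
  }, numeric(1))
  data.frame(strength_nS = strengths_nS, norm_bap = nb)
}

# minimal distal synaptic conductance (Exp2, 0.5/2 ms, 530 um) that triggers
# a calcium spike when paired with the somatically evoked bAP at dt_pair;
# the calcium-current integral at the tuft jumps by orders of magnitude at
# the transition, so "triggered" is integral > max(1, 20 x bare-step value)
.distal_pairing_threshold <- function(model, dt_pair = 5,
                                      resolution_nS = 0.25,
                                      bracket_nS = c(2, 20), t0 = 10) {
  spec <- simulation_spec(duration = t0 + 70)
  ica_int <- function(g) {
    rec <- simulate_protocol(model, make_bac_pairing(dt_pair, g, t0 = t0),
                             spec)
    dt <- rec$time[2] - rec$time[1]
    sum(pmax(-rec$series$tuft650_ica, 0)) * dt
  }
  bare <- ica_int(0)
  cut <- max(1, 20 * bare)
  triggered <- function(g) ica_int(g) > cut
  lo <- bracket_nS[1]; hi <- bracket_nS[2]
  if (triggered(lo)) stop("lower bracket already triggers a calcium spike")
  if (!triggered(hi)) stop("no calcium spike within the bracket")
  while (hi - lo > resolution_nS) {
    mid <- (lo + hi) / 2
    if (triggered(mid)) hi <- mid else lo <- mid
  }
  hi   # the smallest conductance seen to trigger the calcium spike
}
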