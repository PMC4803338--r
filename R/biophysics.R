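# Channel models and spatial density laws.
#
# Gating kinetics follow the published CA1-pyramidal channel models for the
# sodium, delayed-rectifier and A-type potassium currents (Borg-Graham style
# rate laws with the thermodynamic zeta/gamma parameterization), a standard
# high-voltage-activated calcium current (m^2 h), a low-threshold calcium
# current confined to the distal initiation zone, and a calcium-activated
# potassium current driven by a first-order submembrane calcium pool.  The
# calcium-related kinetics and the pool are calibrated so the model expresses
# the target phenomenology: attenuating bAPs, BAC firing, a critical
# frequency for distal calcium spikes, and a bimodal distal calcium signal.

.FARADAY <- 96485.3
.GASCONST <- 8.315

#' Default channel kinetic parameters
#'
#' All rate-law constants of the six channel models, the fixed reversal
#' potentials (E_Na = +60 mV, E_K = -80 mV, E_Ca = +140 mV), the simulation
#' temperature (30 C) and the submembrane calcium pool parameters.  Any entry
#' can be overridden when assembling a model with [build_neuron_model()].
#'
#' @return Named list of kinetic parameters.
#' @export
kinetics_defaults <- function() {
  list(
    celsius = 30,
    e_na = 60, e_k = -80, e_ca = 140,
    # transient Na (m^3 h)
    na_tha = -30, na_qa = 7.2, na_Ra = 0.6, na_Rb = 0.186,
    na_thi1 = -45, na_thi2 = -45, na_qd = 1.5, na_qg = 1.5,
    na_Rd = 0.03, na_Rg = 0.01, na_thinf = -50, na_qinf = 4,
    na_q10 = 1.8, na_tref = 24, na_mmin = 0.02, na_hmin = 0.5,
    # delayed rectifier K (n)
    kdr_vhalfn = 18, kdr_a0n = 0.02, kdr_zetan = -3, kdr_gmn = 0.7,
    # A-type K (n * l), proximal variant
    ka_vhalfn = 11, ka_zetan = -1.5, ka_pw = -1, ka_tq = -40, ka_qq = 5,
    ka_a0n = 0.05, ka_gmn = 0.55, ka_nmin = 0.1,
    ka_q10 = 5, ka_tref = 24,
    ka_vhalfl = -56, ka_zetal = 3, ka_lmin = 2,
    # high-voltage-activated Ca (m^2 h)
    cah_ma_a = 0.055, cah_ma_v = -27, cah_ma_k = 3.8,
    cah_mb_a = 0.94, cah_mb_v = -75, cah_mb_k = 17,
    cah_ha_a = 4.57e-4, cah_ha_v = -13, cah_ha_k = 50,
    cah_hb_a = 0.0065, cah_hb_v = -15, cah_hb_k = 28,
    # low-threshold Ca of the distal initiation zone (m * h)
    cal_vhm = -31.25, cal_km = 5.5, cal_taum = 6,
    cal_vhh = -67, cal_kh = 6.5, cal_tauh = 12.5,
    # calcium-activated K (single gate, calcium-dependent activation)
    kca_kd = 0.5, kca_tau = 8,
    # submembrane calcium pool
    ca_depth_um = 0.1, ca_tau = 30, ca_rest = 5e-5
  )
}

.trap0 <- function(v, th, a, q) {
  ifelse(abs(v - th) > 1e-6 * q,
         a * (v - th) / (1 - exp(-(v - th) / q)),
         a * q)
}

.zexp <- function(zeta, gamma, v, vhalf, celsius) {
  exp(1e-3 * zeta * gamma * (v - vhalf) * .FARADAY /
        (.GASCONST * (273.16 + celsius)))
}

#' Gating steady states and time constants of a channel
#'
#' Evaluates the rate laws of one channel model at a membrane potential (and
#' calcium concentration, for the calcium-activated potassium current).
#' These are the same expressions the compiled integrator uses; the R
#' versions exist for inspection and testing.
#'
#' @param channel One of `"Na"`, `"K_DR"`, `"K_A"`, `"Ca_H"`, `"Ca_L"`,
#'   `"K_Ca"`.
#' @param v Membrane potential, mV (vectorized).
#' @param ca Calcium concentration, mM (required for `"K_Ca"`).
#' @param shift_act,shift_inact Voltage shift (mV) added to the activation /
#'   inactivation rate-law argument; positive shifts move the curves to more
#'   depolarized potentials.
#' @param kin Kinetic parameters, see [kinetics_defaults()].
#' @return Data frame with one row per (voltage, gate): `gate`, `v`, `inf`,
#'   `tau_ms`, `exponent`.
#' @export
channel_gates <- function(channel, v, ca = NULL, shift_act = 0,
                          shift_inact = 0, kin = kinetics_defaults()) {
  k <- kin
  qt <- k$na_q10^((k$celsius - k$na_tref) / 10)
  gate <- function(name, v, inf, tau, expo)
    data.frame(gate = name, v = v, inf = inf, tau_ms = tau, exponent = expo)
  out <- switch(
    channel,
    Na = {
      va <- v - shift_act
      vi <- v - shift_inact
      am <- .trap0(va, k$na_tha, k$na_Ra, k$na_qa)
      bm <- .trap0(-va, -k$na_tha, k$na_Rb, k$na_qa)
      ah <- .trap0(vi, k$na_thi1, k$na_Rd, k$na_qd)
      bh <- .trap0(-vi, -k$na_thi2, k$na_Rg, k$na_qg)
      rbind(
        gate("m", v, am / (am + bm), pmax(1 / (am + bm) / qt, k$na_mmin), 3),
        gate("h", v, 1 / (1 + exp((vi - k$na_thinf) / k$na_qinf)),
             pmax(1 / (ah + bh) / qt, k$na_hmin), 1))
    },
    K_DR = {
      a <- .zexp(k$kdr_zetan, 1, v, k$kdr_vhalfn, k$celsius)
      b <- .zexp(k$kdr_zetan, k$kdr_gmn, v, k$kdr_vhalfn, k$celsius)
      gate("n", v, 1 / (1 + a), b / (k$kdr_a0n * (1 + a)), 1)
    },
    K_A = {
      qtl <- k$ka_q10^((k$celsius - k$ka_tref) / 10)
      zeta <- k$ka_zetan + k$ka_pw / (1 + exp((v - k$ka_tq) / k$ka_qq))
      a <- .zexp(zeta, 1, v, k$ka_vhalfn, k$celsius)
      b <- .zexp(zeta, k$ka_gmn, v, k$ka_vhalfn, k$celsius)
      al <- .zexp(k$ka_zetal, 1, v, k$ka_vhalfl, k$celsius)
      rbind(
        gate("n", v, 1 / (1 + a),
             pmax(b / (qtl * k$ka_a0n * (1 + a)), k$ka_nmin), 1),
        gate("l", v, 1 / (1 + al), pmax(0.26 * (v + 50), k$ka_lmin), 1))
    },
    Ca_H = {
      am <- .trap0(v, k$cah_ma_v, k$cah_ma_a, k$cah_ma_k)
      bm <- k$cah_mb_a * exp((k$cah_mb_v - v) / k$cah_mb_k)
      ah <- k$cah_ha_a * exp((k$cah_ha_v - v) / k$cah_ha_k)
      bh <- k$cah_hb_a / (exp((-v - k$cah_hb_v) / k$cah_hb_k) + 1)
      rbind(gate("m", v, am / (am + bm), 1 / (am + bm), 2),
            gate("h", v, ah / (ah + bh), 1 / (ah + bh), 1))
    },
    Ca_L = {
      rbind(
        gate("m", v, 1 / (1 + exp(-(v - k$cal_vhm) / k$cal_km)), k$cal_taum, 1),
        gate("h", v, 1 / (1 + exp((v - k$cal_vhh) / k$cal_kh)), k$cal_tauh, 1))
    },
    K_Ca = {
      if (is.null(ca)) stop("K_Ca gating requires a calcium concentration")
      gate("m", v, ca / (ca + k$kca_kd), k$kca_tau, 1)
    },
    stop("unknown channel: ", channel)
  )
  rownames(out) <- NULL
  out
}

#' A-type potassium conductance density as a function of distance
#'
#' The A-type conductance increases linearly five-fold from its somatic value
#' of 0.029 S/cm^2 at the soma to 5 x 0.029 S/cm^2 at 500 um along the apical
#' path, and is clamped at the 500-um value beyond.
#'
#' @param distance_um Path distance from the soma, um (vectorized, >= 0).
#' @param g0 Somatic density, S/cm^2.
#' @param fold Fold increase reached at `ramp_um`.
#' @param ramp_um Distance at which the ramp ends.
#' @return Conductance density in S/cm^2.
#' @examples
#' ka_density(c(0, 250, 500, 600))
#' @export
ka_density <- function(distance_um, g0 = 0.029, fold = 5, ramp_um = 500) {
  if (any(distance_um < 0)) stop("negative distance")
  g0 * (1 + (fold - 1) * pmin(distance_um, ramp_um) / ramp_um)
}

#' Default maximal conductance densities and placement rules
#'
#' @return Named list of the density parameters (S/cm^2 unless noted) used by
#'   [assemble_channel_distribution()].
#' @export
channel_defaults <- function() {
  list(
    gna_dend = 0.009, gkdr_dend = 0.01,
    dend_na_shift = 5,              # mV, dendritic Na activation shift
    gka0 = 0.029, ka_fold = 5, ka_ramp_um = 500,
    gcah = 0.00015, gkca = 0.00025,
    ca_zone = c(500, 750),          # um along the apical path
    cah_zone_mult = 3, gcal_zone = 0.005,
    soma_ca_mult = 2,
    gna_axon_total = 0.6,           # split 50/50 between shifted/unshifted
    axon_na_shift = -10             # mV, applied to half the axonal channels
  )
}

#' Assemble the per-segment channel density map
#'
#' Applies the spatial rules to a morphology: uniform dendritic Na (activation
#' shifted +5 mV) and delayed-rectifier K; an A-type K gradient along the
#' apical path (basal sections use the somatic value); high-voltage-activated
#' Ca, Ca-activated K and the calcium pool in all dendrites and the soma
#' (2-fold Ca_H and K_Ca at the soma); a calcium-spike initiation zone at
#' 500-750 um on the apical tuft with 3-fold Ca_H and the low-threshold Ca
#' current; and an axon initial segment carrying 0.6 S/cm^2 Na in total, half
#' of it with kinetics shifted by -10 mV.
#'
#' @param morph A `pyr_morphology`.
#' @param overrides Named list overriding entries of [channel_defaults()].
#' @return Data frame aligned with `morph$segs`, one row per segment, with
#'   conductance densities in S/cm^2 and the Na voltage shifts in mV.
#' @export
assemble_channel_distribution <- function(morph, overrides = list()) {
  p <- channel_defaults()
  bad <- setdiff(names(overrides), names(p))
  if (length(bad)) stop("unknown channel parameter(s): ", paste(bad, collapse = ", "))
  p[names(overrides)] <- overrides
  if (p$ca_zone[1] > p$ca_zone[2]) stop("invalid calcium zone")
  segs <- morph$segs
  apical_max <- max(segs$dist_um[segs$kind %in% c("trunk", "oblique", "tuft")])
  if (p$ca_zone[1] > apical_max) stop("calcium zone outside the apical tree")

  n <- nrow(segs)
  d <- data.frame(
    seg_id = segs$seg_id, section = segs$section, kind = segs$kind,
    dist_um = segs$dist_um,
    gna = 0, na_shift = 0, gna2 = 0, na2_shift = 0,
    gkdr = 0, gka = 0, gcah = 0, gcal = 0, gkca = 0,
    has_ca_pool = FALSE, stringsAsFactors = FALSE)

  dend <- segs$kind %in% c("trunk", "oblique", "tuft", "basal")
  soma <- segs$kind == "soma"
  axon <- segs$kind == "axon"
  apical <- segs$kind %in% c("trunk", "oblique", "tuft")

  d$gna[dend] <- p$gna_dend
  d$na_shift[dend] <- p$dend_na_shift
  d$gkdr[dend] <- p$gkdr_dend
  d$gka[apical] <- ka_density(segs$dist_um[apical], p$gka0, p$ka_fold,
                              p$ka_ramp_um)
  d$gka[segs$kind == "basal"] <- p$gka0
  d$gcah[dend] <- p$gcah
  d$gkca[dend] <- p$gkca
  zone <- segs$kind == "tuft" & segs$dist_um >= p$ca_zone[1] &
    segs$dist_um <= p$ca_zone[2]
  d$gcah[zone] <- p$gcah * p$cah_zone_mult
  d$gcal[zone] <- p$gcal_zone

  d$gna[soma] <- p$gna_dend
  d$gkdr[soma] <- p$gkdr_dend
  d$gka[soma] <- p$gka0
  d$gcah[soma] <- p$gcah * p$soma_ca_mult
  d$gkca[soma] <- p$gkca * p$soma_ca_mult

  d$gna[axon] <- p$gna_axon_total / 2
  d$gna2[axon] <- p$gna_axon_total / 2
  d$na2_shift[axon] <- p$axon_na_shift
  d$gkdr[axon] <- p$gkdr_dend

  d$has_ca_pool <- d$gcah + d$gcal > 0
  attr(d, "params") <- p
  d
}

#' Total membrane current density from channel states
#'
#' Reference conductance-based current summation: each channel contributes
#' `g * prod(gates^exponent) * (V - E_rev)` and the leak contributes
#' `(V - E_L) / R_m`.  Used as an independently checkable mirror of the
#' compiled integrator's current assembly.
#'
#' @param v Membrane potential, mV.
#' @param gates Named list of gate states in `[0, 1]`:
#'   `na_m, na_h, kdr_n, ka_n, ka_l, cah_m, cah_h, cal_m, cal_h, kca_m`.
#' @param ca Calcium concentration, mM (unused in the current sum itself; the
#'   calcium reversal is fixed).
#' @param dens One row of [assemble_channel_distribution()] output (or any
#'   list with the same conductance fields, S/cm^2).
#' @param passive List with `rm` (Ohm cm^2) and `el` (mV).
#' @param kin Kinetic parameters (for the reversal potentials).
#' @return Named numeric vector of current densities (mA/cm^2) per channel,
#'   including `leak` and the `total`.
#' @export
membrane_current <- function(v, gates, ca, dens, passive,
                             kin = kinetics_defaults()) {
  g <- gates
  stopifnot(all(unlist(g) >= 0), all(unlist(g) <= 1))
  i_na <- (dens$gna + dens$gna2) * g$na_m^3 * g$na_h * (v - kin$e_na)
  i_kdr <- dens$gkdr * g$kdr_n * (v - kin$e_k)
  i_ka <- dens$gka * g$ka_n * g$ka_l * (v - kin$e_k)
  i_cah <- dens$gcah * g$cah_m^2 * g$cah_h * (v - kin$e_ca)
  i_cal <- dens$gcal * g$cal_m * g$cal_h * (v - kin$e_ca)
  i_kca <- dens$gkca * g$kca_m * (v - kin$e_k)
  i_leak <- (v - passive$el) / passive$rm
  out <- c(Na = i_na, K_DR = i_kdr, K_A = i_ka, Ca_H = i_cah,
           Ca_L = i_cal, K_Ca = i_kca, leak = i_leak)
  c(out, total = sum(out))
}
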