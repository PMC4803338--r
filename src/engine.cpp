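// Implicit (backward-Euler) integrator for the branched cable equation with
// Hodgkin-Huxley style channels, conductance synapses and an optional
// single-compartment fast-spiking interneuron coupled by an event (spike ->
// delayed shunting conductance on the pyramidal cell).
//
// The tree is supplied in parent-before-child (Hines) order, so the linear
// system solved each step is eliminated leaf-to-root and back-substituted
// root-to-leaf in O(N).  Gating variables advance by exact exponential
// relaxation at the voltage of the previous step (the staggered update used
// by standard compartmental simulators); membrane currents then enter the
// voltage solve as linear conductances, which keeps the step unconditionally
// stable at dt = 0.1 ms.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double FARADAY = 96485.3;
static const double GASCONST = 8.315;

struct Kin {
  double celsius, e_na, e_k, e_ca;
  double na_tha, na_qa, na_Ra, na_Rb, na_thi1, na_thi2, na_qd, na_qg;
  double na_Rd, na_Rg, na_thinf, na_qinf, na_q10, na_tref, na_mmin, na_hmin;
  double kdr_vhalfn, kdr_a0n, kdr_zetan, kdr_gmn;
  double ka_vhalfn, ka_zetan, ka_pw, ka_tq, ka_qq, ka_a0n, ka_gmn, ka_nmin;
  double ka_q10, ka_tref, ka_vhalfl, ka_zetal, ka_lmin;
  double cah_ma_a, cah_ma_v, cah_ma_k, cah_mb_a, cah_mb_v, cah_mb_k;
  double cah_ha_a, cah_ha_v, cah_ha_k, cah_hb_a, cah_hb_v, cah_hb_k;
  double cal_vhm, cal_km, cal_taum, cal_vhh, cal_kh, cal_tauh;
  double kca_kd, kca_tau;
  double ca_depth_um, ca_tau, ca_rest;
  double qt, ka_qtl, zfac; // derived
};

static Kin read_kin(const List& k) {
  Kin K;
#define GET(f) K.f = as<double>(k[#f])
  GET(celsius); GET(e_na); GET(e_k); GET(e_ca);
  GET(na_tha); GET(na_qa); GET(na_Ra); GET(na_Rb); GET(na_thi1); GET(na_thi2);
  GET(na_qd); GET(na_qg); GET(na_Rd); GET(na_Rg); GET(na_thinf); GET(na_qinf);
  GET(na_q10); GET(na_tref); GET(na_mmin); GET(na_hmin);
  GET(kdr_vhalfn); GET(kdr_a0n); GET(kdr_zetan); GET(kdr_gmn);
  GET(ka_vhalfn); GET(ka_zetan); GET(ka_pw); GET(ka_tq); GET(ka_qq);
  GET(ka_a0n); GET(ka_gmn); GET(ka_nmin); GET(ka_q10); GET(ka_tref);
  GET(ka_vhalfl); GET(ka_zetal); GET(ka_lmin);
  GET(cah_ma_a); GET(cah_ma_v); GET(cah_ma_k);
  GET(cah_mb_a); GET(cah_mb_v); GET(cah_mb_k);
  GET(cah_ha_a); GET(cah_ha_v); GET(cah_ha_k);
  GET(cah_hb_a); GET(cah_hb_v); GET(cah_hb_k);
  GET(cal_vhm); GET(cal_km); GET(cal_taum); GET(cal_vhh); GET(cal_kh);
  GET(cal_tauh);
  GET(kca_kd); GET(kca_tau);
  GET(ca_depth_um); GET(ca_tau); GET(ca_rest);
#undef GET
  K.qt = std::pow(K.na_q10, (K.celsius - K.na_tref) / 10.0);
  K.ka_qtl = std::pow(K.ka_q10, (K.celsius - K.ka_tref) / 10.0);
  K.zfac = 1e-3 * FARADAY / (GASCONST * (273.16 + K.celsius));
  return K;
}

static inline double trap0(double v, double th, double a, double q) {
  double x = v - th;
  if (std::fabs(x) > 1e-6 * q) return a * x / (1.0 - std::exp(-x / q));
  return a * q;
}

struct InfTau { double inf, tau; };

static inline InfTau na_m(const Kin& K, double v) {
  double am = trap0(v, K.na_tha, K.na_Ra, K.na_qa);
  double bm = trap0(-v, -K.na_tha, K.na_Rb, K.na_qa);
  InfTau r;
  r.inf = am / (am + bm);
  r.tau = std::max(1.0 / (am + bm) / K.qt, K.na_mmin);
  return r;
}
static inline InfTau na_h(const Kin& K, double v) {
  double ah = trap0(v, K.na_thi1, K.na_Rd, K.na_qd);
  double bh = trap0(-v, -K.na_thi2, K.na_Rg, K.na_qg);
  InfTau r;
  r.inf = 1.0 / (1.0 + std::exp((v - K.na_thinf) / K.na_qinf));
  r.tau = std::max(1.0 / (ah + bh) / K.qt, K.na_hmin);
  return r;
}
static inline InfTau kdr_n(const Kin& K, double v) {
  double a = std::exp(K.kdr_zetan * K.zfac * (v - K.kdr_vhalfn));
  double b = std::exp(K.kdr_zetan * K.kdr_gmn * K.zfac * (v - K.kdr_vhalfn));
  InfTau r;
  r.inf = 1.0 / (1.0 + a);
  r.tau = b / (K.kdr_a0n * (1.0 + a));
  return r;
}
static inline InfTau ka_n(const Kin& K, double v) {
  double zeta = K.ka_zetan + K.ka_pw / (1.0 + std::exp((v - K.ka_tq) / K.ka_qq));
  double a = std::exp(zeta * K.zfac * (v - K.ka_vhalfn));
  double b = std::exp(zeta * K.ka_gmn * K.zfac * (v - K.ka_vhalfn));
  InfTau r;
  r.inf = 1.0 / (1.0 + a);
  r.tau = std::max(b / (K.ka_qtl * K.ka_a0n * (1.0 + a)), K.ka_nmin);
  return r;
}
static inline InfTau ka_l(const Kin& K, double v) {
  double al = std::exp(K.ka_zetal * K.zfac * (v - K.ka_vhalfl));
  InfTau r;
  r.inf = 1.0 / (1.0 + al);
  r.tau = std::max(0.26 * (v + 50.0), K.ka_lmin);
  return r;
}
static inline InfTau cah_m(const Kin& K, double v) {
  double am = trap0(v, K.cah_ma_v, K.cah_ma_a, K.cah_ma_k);
  double bm = K.cah_mb_a * std::exp((K.cah_mb_v - v) / K.cah_mb_k);
  InfTau r; r.inf = am / (am + bm); r.tau = 1.0 / (am + bm); return r;
}
static inline InfTau cah_h(const Kin& K, double v) {
  double ah = K.cah_ha_a * std::exp((K.cah_ha_v - v) / K.cah_ha_k);
  double bh = K.cah_hb_a / (std::exp((-v - K.cah_hb_v) / K.cah_hb_k) + 1.0);
  InfTau r; r.inf = ah / (ah + bh); r.tau = 1.0 / (ah + bh); return r;
}
static inline InfTau cal_m(const Kin& K, double v) {
  InfTau r;
  r.inf = 1.0 / (1.0 + std::exp(-(v - K.cal_vhm) / K.cal_km));
  r.tau = K.cal_taum;
  return r;
}
static inline InfTau cal_h(const Kin& K, double v) {
  InfTau r;
  r.inf = 1.0 / (1.0 + std::exp((v - K.cal_vhh) / K.cal_kh));
  r.tau = K.cal_tauh;
  return r;
}
static inline InfTau kca_m(const Kin& K, double ca) {
  InfTau r;
  r.inf = ca / (ca + K.kca_kd);
  r.tau = K.kca_tau;
  return r;
}

static inline double relax(double x, double inf, double tau, double dt) {
  return inf + (x - inf) * std::exp(-dt / tau);
}

// ---- synapse bookkeeping -------------------------------------------------

struct Syn {
  int seg;          // 0-based segment index, -1 for the interneuron itself
  int type;         // 2 = double exponential, 1 = single exponential
  double tau_r, tau_d, gmax, erev, factor;
  std::vector<double> onsets; // sorted
  size_t next;
  double A, B;      // states; g = B - A (exp2) or B (exp1)
  double decay_r, decay_d;
  void init(double dt) {
    next = 0; A = 0.0; B = 0.0;
    decay_d = std::exp(-dt / tau_d);
    decay_r = (type == 2) ? std::exp(-dt / tau_r) : 0.0;
    if (type == 2) {
      double tp = tau_r * tau_d / (tau_d - tau_r) * std::log(tau_d / tau_r);
      factor = 1.0 / (std::exp(-tp / tau_d) - std::exp(-tp / tau_r));
    } else {
      factor = 1.0;
    }
  }
  void step(double t_new) {
    B *= decay_d;
    if (type == 2) A *= decay_r;
    while (next < onsets.size() && onsets[next] <= t_new + 1e-9) {
      B += gmax * factor;
      if (type == 2) A += gmax * factor;
      ++next;
    }
  }
  double g() const { return (type == 2) ? (B - A) : B; }
};

// ---- interneuron (Wang-Buzsaki fast-spiking cell) ------------------------

struct Interneuron {
  bool present = false, active = true;
  double area, cm_nf, gna, gk, gl; // conductances in uS (density * area)
  double el, ena, ek, phi, a_scale, b_scale;
  double v, m, h, n;
  Syn syn;           // EX -> IN drive
  double thresh, delay;
  double spike_time; // first upward crossing of thresh; NA if none
  bool spiked = false;

  void rates(double vv, InfTau& rm, InfTau& rh, InfTau& rn) const {
    double am = a_scale * 0.1 * trap0(vv, -35.0, 1.0, 10.0);
    double bm = b_scale * 4.0 * std::exp(-(vv + 60.0) / 18.0);
    rm.inf = am / (am + bm); rm.tau = 1.0 / (am + bm);
    double ah = phi * 0.07 * std::exp(-(vv + 58.0) / 20.0);
    double bh = phi / (std::exp(-0.1 * (vv + 28.0)) + 1.0);
    rh.inf = ah / (ah + bh); rh.tau = 1.0 / (ah + bh);
    double an = phi * 0.1 * trap0(vv, -34.0, 1.0, 10.0) * 0.1;
    double bn = phi * 0.125 * std::exp(-(vv + 44.0) / 80.0);
    rn.inf = an / (an + bn); rn.tau = 1.0 / (an + bn);
  }

  void step(double t_new, double dt) {
    InfTau rm, rh, rn;
    rates(v, rm, rh, rn);
    m = rm.inf;     // activation is instantaneous in this cell model
    h = relax(h, rh.inf, rh.tau, dt);
    n = relax(n, rn.inf, rn.tau, dt);
    syn.step(t_new);
    double gna_t = gna * m * m * m * h;
    double gk_t = gk * n * n * n * n;
    double gs = syn.g();
    double num = cm_nf / dt * v + gna_t * ena + gk_t * ek + gl * el +
      gs * syn.erev;
    double den = cm_nf / dt + gna_t + gk_t + gl + gs;
    double v_new = num / den;
    if (!spiked && v < thresh && v_new >= thresh) {
      spiked = true;
      spike_time = t_new;
    }
    v = v_new;
  }
};

// ---- main entry ----------------------------------------------------------

// state vector layout: 14 * N cell variables + 4 interneuron variables
// (V, na_m, na_h, na2_m, na2_h, kdr_n, ka_n, ka_l, cah_m, cah_h, cal_m,
//  cal_h, kca_m, ca) then (in_v, in_m, in_h, in_n)

// [[Rcpp::export(name = ".engine_run")]]
List engine_run(List model, List stim, List spec,
                Nullable<NumericVector> state0 = R_NilValue) {
  const IntegerVector parent = model["parent"];
  const NumericVector cm_nf = model["cm_nf"];
  const NumericVector g_ax = model["g_ax"];
  const NumericVector area = model["area_cm2"];
  const NumericVector gna = model["gna_uS"];
  const NumericVector gna2 = model["gna2_uS"];
  const NumericVector na_shift = model["na_shift"];
  const NumericVector na2_shift = model["na2_shift"];
  const NumericVector gkdr = model["gkdr_uS"];
  const NumericVector gka = model["gka_uS"];
  const NumericVector gcah = model["gcah_uS"];
  const NumericVector gcal = model["gcal_uS"];
  const NumericVector gkca = model["gkca_uS"];
  const NumericVector gleak = model["gleak_uS"];
  const double el = as<double>(model["el"]);
  const Kin K = read_kin(model["kin"]);
  const int N = parent.size();

  const double dt = as<double>(spec["dt"]);
  const double duration = as<double>(spec["duration"]);
  const double v_init = as<double>(spec["v_init"]);
  const int nt = (int)std::lround(duration / dt);

  // probes
  IntegerVector probe_seg = spec["probe_seg"];       // 0-based; -2 = interneuron V
  IntegerVector probe_qty = spec["probe_qty"];       // 0 V, 1 ICa, 2 Ca, 3 gsyn
  const int np = probe_seg.size();

  // stimuli
  NumericMatrix steps = stim["steps"];               // seg, onset, dur, amp_nA
  List syn_list = stim["synapses"];
  std::vector<Syn> syns(syn_list.size());
  for (int s = 0; s < (int)syn_list.size(); ++s) {
    List sl = syn_list[s];
    syns[s].seg = as<int>(sl["seg"]);
    syns[s].type = as<int>(sl["type"]);
    syns[s].tau_r = as<double>(sl["tau_r"]);
    syns[s].tau_d = as<double>(sl["tau_d"]);
    syns[s].gmax = as<double>(sl["gmax_uS"]);
    syns[s].erev = as<double>(sl["erev"]);
    syns[s].onsets = as<std::vector<double>>(sl["onsets"]);
    syns[s].init(dt);
  }

  // optional interneuron with event-driven output synapse
  Interneuron in;
  int in_out_syn = -1;
  if (stim.containsElementNamed("interneuron") &&
      !Rf_isNull(stim["interneuron"])) {
    List il = stim["interneuron"];
    in.present = true;
    in.active = as<bool>(il["active"]);
    in.area = as<double>(il["area_cm2"]);
    in.cm_nf = as<double>(il["cm"]) * in.area * 1e3;
    in.gna = as<double>(il["gna_dens"]) * in.area * 1e6;
    in.gk = as<double>(il["gk_dens"]) * in.area * 1e6;
    in.gl = as<double>(il["gl_dens"]) * in.area * 1e6;
    in.el = as<double>(il["el"]);
    in.ena = as<double>(il["ena"]);
    in.ek = as<double>(il["ek"]);
    in.phi = as<double>(il["phi"]);
    in.a_scale = as<double>(il["a_scale"]);
    in.b_scale = as<double>(il["b_scale"]);
    in.thresh = as<double>(il["thresh"]);
    in.delay = as<double>(il["delay"]);
    in.spike_time = NA_REAL;
    List es = il["drive"];
    in.syn.seg = -1;
    in.syn.type = 2;
    in.syn.tau_r = as<double>(es["tau_r"]);
    in.syn.tau_d = as<double>(es["tau_d"]);
    in.syn.gmax = as<double>(es["gmax_uS"]);
    in.syn.erev = as<double>(es["erev"]);
    in.syn.onsets = as<std::vector<double>>(es["onsets"]);
    in.syn.init(dt);
    in_out_syn = as<int>(il["out_syn_index"]); // index into syns, events added at spike
  }

  // state
  std::vector<double> V(N), ca(N);
  std::vector<double> m1(N), h1(N), m2(N), h2(N), nk(N), an(N), al(N);
  std::vector<double> chm(N), chh(N), clm(N), clh(N), km(N);
  bool fresh = state0.isNull();
  if (fresh) {
    for (int i = 0; i < N; ++i) {
      V[i] = v_init;
      ca[i] = K.ca_rest;
      m1[i] = na_m(K, v_init - na_shift[i]).inf;
      h1[i] = na_h(K, v_init).inf;
      m2[i] = na_m(K, v_init - na2_shift[i]).inf;
      h2[i] = na_h(K, v_init - na2_shift[i]).inf;
      nk[i] = kdr_n(K, v_init).inf;
      an[i] = ka_n(K, v_init).inf;
      al[i] = ka_l(K, v_init).inf;
      chm[i] = cah_m(K, v_init).inf;
      chh[i] = cah_h(K, v_init).inf;
      clm[i] = cal_m(K, v_init).inf;
      clh[i] = cal_h(K, v_init).inf;
      km[i] = kca_m(K, ca[i]).inf;
    }
  } else {
    NumericVector s0(state0);
    if ((int)s0.size() != 14 * N + 4) stop("state vector has wrong length");
    const double* p = s0.begin();
    for (int i = 0; i < N; ++i) {
      V[i] = p[i]; m1[i] = p[N + i]; h1[i] = p[2 * N + i];
      m2[i] = p[3 * N + i]; h2[i] = p[4 * N + i]; nk[i] = p[5 * N + i];
      an[i] = p[6 * N + i]; al[i] = p[7 * N + i]; chm[i] = p[8 * N + i];
      chh[i] = p[9 * N + i]; clm[i] = p[10 * N + i]; clh[i] = p[11 * N + i];
      km[i] = p[12 * N + i]; ca[i] = p[13 * N + i];
    }
    if (in.present) {
      in.v = s0[14 * N]; in.m = s0[14 * N + 1];
      in.h = s0[14 * N + 2]; in.n = s0[14 * N + 3];
      // a state saved without an interneuron: start the cell at its own rest
      if (in.v == 0.0 && in.m == 0.0 && in.h == 0.0 && in.n == 0.0)
        fresh = true;
    }
  }
  if (in.present && fresh) {
    in.v = in.el;
    InfTau rm, rh, rn;
    in.rates(in.v, rm, rh, rn);
    in.m = rm.inf; in.h = rh.inf; in.n = rn.inf;
  }

  NumericMatrix out(nt + 1, np);
  NumericVector tgrid(nt + 1);
  std::vector<double> gsyn_node(N, 0.0);

  auto record = [&](int row) {
    for (int pq = 0; pq < np; ++pq) {
      int sgi = probe_seg[pq];
      double val = NA_REAL;
      if (sgi == -2) {
        val = in.present ? in.v : NA_REAL;
      } else {
        switch (probe_qty[pq]) {
        case 0: val = V[sgi]; break;
        case 1: { // calcium current density, mA/cm^2
          double g = gcah[sgi] * chm[sgi] * chm[sgi] * chh[sgi] +
            gcal[sgi] * clm[sgi] * clh[sgi];
          val = g * (V[sgi] - K.e_ca) / (area[sgi] * 1e6);
          break; }
        case 2: val = ca[sgi]; break;
        case 3: val = gsyn_node[sgi]; break;
        }
      }
      out(row, pq) = val;
    }
  };
  record(0);
  tgrid[0] = 0.0;

  std::vector<double> d(N), rhs(N);
  const double ca_k = 1e4 / (2.0 * FARADAY * K.ca_depth_um);

  double t = 0.0;
  for (int it = 1; it <= nt; ++it) {
    double t_new = it * dt;
    // gating update at old V
    for (int i = 0; i < N; ++i) {
      double v = V[i];
      if (gna[i] > 0.0) {
        InfTau rm = na_m(K, v - na_shift[i]);
        InfTau rh = na_h(K, v);
        m1[i] = relax(m1[i], rm.inf, rm.tau, dt);
        h1[i] = relax(h1[i], rh.inf, rh.tau, dt);
      }
      if (gna2[i] > 0.0) {
        InfTau rm = na_m(K, v - na2_shift[i]);
        InfTau rh = na_h(K, v - na2_shift[i]);
        m2[i] = relax(m2[i], rm.inf, rm.tau, dt);
        h2[i] = relax(h2[i], rh.inf, rh.tau, dt);
      }
      if (gkdr[i] > 0.0) {
        InfTau r = kdr_n(K, v);
        nk[i] = relax(nk[i], r.inf, r.tau, dt);
      }
      if (gka[i] > 0.0) {
        InfTau rn = ka_n(K, v), rl = ka_l(K, v);
        an[i] = relax(an[i], rn.inf, rn.tau, dt);
        al[i] = relax(al[i], rl.inf, rl.tau, dt);
      }
      if (gcah[i] > 0.0 || gcal[i] > 0.0) {
        InfTau rm = cah_m(K, v), rh = cah_h(K, v);
        chm[i] = relax(chm[i], rm.inf, rm.tau, dt);
        chh[i] = relax(chh[i], rh.inf, rh.tau, dt);
        if (gcal[i] > 0.0) {
          InfTau lm = cal_m(K, v), lh = cal_h(K, v);
          clm[i] = relax(clm[i], lm.inf, lm.tau, dt);
          clh[i] = relax(clh[i], lh.inf, lh.tau, dt);
        }
      }
      if (gkca[i] > 0.0) {
        InfTau r = kca_m(K, ca[i]);
        km[i] = relax(km[i], r.inf, r.tau, dt);
      }
    }

    // assemble diagonal and rhs
    for (int i = 0; i < N; ++i) {
      double gsum = gleak[i];
      double gesum = gleak[i] * el;
      if (gna[i] > 0.0) {
        double g = gna[i] * m1[i] * m1[i] * m1[i] * h1[i];
        gsum += g; gesum += g * K.e_na;
      }
      if (gna2[i] > 0.0) {
        double g = gna2[i] * m2[i] * m2[i] * m2[i] * h2[i];
        gsum += g; gesum += g * K.e_na;
      }
      if (gkdr[i] > 0.0) {
        double g = gkdr[i] * nk[i];
        gsum += g; gesum += g * K.e_k;
      }
      if (gka[i] > 0.0) {
        double g = gka[i] * an[i] * al[i];
        gsum += g; gesum += g * K.e_k;
      }
      if (gcah[i] > 0.0) {
        double g = gcah[i] * chm[i] * chm[i] * chh[i];
        gsum += g; gesum += g * K.e_ca;
      }
      if (gcal[i] > 0.0) {
        double g = gcal[i] * clm[i] * clh[i];
        gsum += g; gesum += g * K.e_ca;
      }
      if (gkca[i] > 0.0) {
        double g = gkca[i] * km[i];
        gsum += g; gesum += g * K.e_k;
      }
      d[i] = cm_nf[i] / dt + gsum;
      rhs[i] = cm_nf[i] / dt * V[i] + gesum;
      gsyn_node[i] = 0.0;
    }

    // synapses (conductances evaluated at the new time)
    for (auto& s : syns) {
      s.step(t_new);
      double g = s.g();
      if (g != 0.0) {
        d[s.seg] += g;
        rhs[s.seg] += g * s.erev;
        gsyn_node[s.seg] += g;
      }
    }

    // step currents (nA)
    for (int r = 0; r < steps.nrow(); ++r) {
      if (t_new > steps(r, 1) + 1e-9 &&
          t_new <= steps(r, 1) + steps(r, 2) + 1e-9)
        rhs[(int)steps(r, 0)] += steps(r, 3);
    }

    // axial terms + Hines elimination (children have larger indices)
    for (int i = 1; i < N; ++i) {
      d[i] += g_ax[i];
      d[parent[i]] += g_ax[i];
    }
    for (int i = N - 1; i >= 1; --i) {
      double f = g_ax[i] / d[i];
      d[parent[i]] -= f * g_ax[i];
      rhs[parent[i]] += f * rhs[i];
    }
    V[0] = rhs[0] / d[0];
    for (int i = 1; i < N; ++i)
      V[i] = (rhs[i] + g_ax[i] * V[parent[i]]) / d[i];

    // calcium pool (influx only, exponential relaxation of the decay)
    for (int i = 0; i < N; ++i) {
      if (gcah[i] > 0.0 || gcal[i] > 0.0) {
        double g = gcah[i] * chm[i] * chm[i] * chh[i] +
          gcal[i] * clm[i] * clh[i];
        double ica = g * (V[i] - K.e_ca) / (area[i] * 1e6); // mA/cm^2
        double drive = -ca_k * ica;
        if (drive < 0.0) drive = 0.0;
        double target = K.ca_rest + drive * K.ca_tau;
        ca[i] = target + (ca[i] - target) * std::exp(-dt / K.ca_tau);
      }
    }

    // interneuron: step and (on first spike) schedule its output event
    if (in.present) {
      bool before = in.spiked;
      in.step(t_new, dt);
      if (!before && in.spiked && in.active && in_out_syn >= 0) {
        syns[in_out_syn].onsets.push_back(in.spike_time + in.delay);
      }
    }

    if (!std::isfinite(V[0]))
      stop("non-finite membrane potential at t = %f ms (segment 0)", t_new);
    t = t_new;
    tgrid[it] = t_new;
    record(it);
  }

  for (int i = 0; i < N; ++i)
    if (!std::isfinite(V[i]))
      stop("non-finite membrane potential at end of run (segment %d)", i);

  // pack final state
  NumericVector state(14 * N + 4);
  for (int i = 0; i < N; ++i) {
    state[i] = V[i]; state[N + i] = m1[i]; state[2 * N + i] = h1[i];
    state[3 * N + i] = m2[i]; state[4 * N + i] = h2[i];
    state[5 * N + i] = nk[i]; state[6 * N + i] = an[i];
    state[7 * N + i] = al[i]; state[8 * N + i] = chm[i];
    state[9 * N + i] = chh[i]; state[10 * N + i] = clm[i];
    state[11 * N + i] = clh[i]; state[12 * N + i] = km[i];
    state[13 * N + i] = ca[i];
  }
  if (in.present) {
    state[14 * N] = in.v; state[14 * N + 1] = in.m;
    state[14 * N + 2] = in.h; state[14 * N + 3] = in.n;
  }

  return List::create(
    _["time"] = tgrid,
    _["series"] = out,
    _["state"] = state,
    _["in_spike_time"] = in.present ? wrap(in.spike_time) : R_NilValue);
}
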