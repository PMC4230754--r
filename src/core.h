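#ifndef NMSTAND_CORE_H
#define NMSTAND_CORE_H
// Core numerical engine: spinal neuron pools with kinetic synapses, Hill-type
// musculotendon units, muscle spindle / Golgi tendon organ receptor models,
// stochastic point-process encoders and the single-link inverted pendulum,
// advanced on a common fixed-step RK4 clock.
//
// Unit conventions:
//   neurons: mV (relative to rest), nA, uS, nF, ms
//   mechanics: normalised fibre length (L0), L0/s, N, Nm, rad, s
//   synapse kinetics: 1/ms; conductance banks in uS

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <random>
using namespace Rcpp;

static const double E_NA = 120.0, E_K = -10.0;   // mV relative to rest

// ---------------------------------------------------------------------------
// Musculotendon curves
// ---------------------------------------------------------------------------

struct MTUPar {
  double F0, L0_m, mass, k_pe, b_pe, strain, sin_a0, Lt1_m, c_t, k_t, L_r;
  double a[5], b[5];  // kinematic polynomials (cm, deg)
};

static inline double pe_elastic(double L, const MTUPar& p) {
  return (std::exp(p.k_pe * (L - 1.0) / p.strain) - 1.0) / (std::exp(p.k_pe) - 1.0);
}

static inline double tendon_force_norm(double Lt, double c_t, double k_t, double L_r) {
  double x = (Lt - L_r) / c_t;
  double v = (x > 30.0) ? (k_t * c_t * x) : (k_t * c_t * std::log1p(std::exp(x)));
  return v > 0.0 ? v : 0.0;
}

struct FibreCurve { double beta, omega, rho, vmax, cv0, cv1, av0, av1, av2, bv; };

static inline double fl_curve(double L, const FibreCurve& c) {
  double z = (std::pow(L, c.beta) - 1.0) / c.omega;
  return std::exp(-std::pow(std::fabs(z), c.rho));
}

static inline double fv_curve(double L, double V, const FibreCurve& c) {
  double f;
  if (V <= 0.0) {
    double den = c.vmax + (c.cv0 + c.cv1 * L) * V;
    f = (den >= -1e-12) ? 0.0 : (c.vmax - V) / den;
  } else {
    double a = c.av0 + c.av1 * L + c.av2 * L * L;
    f = (c.bv - a * V) / (c.bv + V);
  }
  return f < 0.0 ? 0.0 : f;
}

// constant-thickness pinnation; returns false on geometric impossibility
static inline bool pinnation(double L, const MTUPar& p, double& sin_a, double& cos_a) {
  sin_a = p.sin_a0 / L;
  if (sin_a >= 1.0 || sin_a <= 0.0) return false;
  cos_a = std::sqrt(1.0 - sin_a * sin_a);
  return true;
}

// fibre state derivative at (L [L0], V [L0/s]) under MTU length Lmtu_m and
// activations; also returns tendon force (normalised) via Ft
static inline bool fibre_deriv(double L, double V, double Lmtu_m,
                               double a_slow, double a_fast,
                               const MTUPar& p, const FibreCurve& cs,
                               const FibreCurve& cf,
                               double& dV, double& Ft) {
  double sin_a, cos_a;
  if (!pinnation(L, p, sin_a, cos_a)) return false;
  double Lt = (Lmtu_m - L * p.L0_m * cos_a) / p.Lt1_m;
  Ft = tendon_force_norm(Lt, p.c_t, p.k_t, p.L_r);
  double Fpe = pe_elastic(L, p) + p.b_pe * V;
  double Fce = a_slow * fl_curve(L, cs) * fv_curve(L, V, cs)
             + a_fast * fl_curve(L, cf) * fv_curve(L, V, cf);
  dV = p.F0 * (Ft - cos_a * (Fce + Fpe)) / (p.mass * p.L0_m);
  return true;
}

static inline double poly4(const double* c, double x) {
  return c[0] + x * (c[1] + x * (c[2] + x * (c[3] + x * c[4])));
}

// ---------------------------------------------------------------------------
// Muscle spindle (bag1 / bag2 / chain intrafusal fibres)
// ---------------------------------------------------------------------------

struct IntrafusalPar {
  double tau, freq, p, beta0, beta1, beta2, G1, G2; // G1=Gamma1, G2=Gamma2
  double C_L, C_S, K_SR, K_PR, M, L0_SR, L0_PR, LN_SR, LN_PR, R, a_pow;
  double Gpri, Gsec, X, L_sec;
};

struct IntrafusalState { double f, T, Td; };

static inline void intrafusal_deriv(const IntrafusalState& s, double gamma,
                                    double L, double V, double A,
                                    const IntrafusalPar& p,
                                    double& df, double& dT, double& dTd) {
  double gp = std::pow(gamma, p.p);
  double fss = gp / (gp + std::pow(p.freq, p.p));
  df = (p.tau <= 1e-3) ? 0.0 : (fss - s.f) / p.tau;
  double f = (p.tau <= 1e-3) ? fss : s.f;
  double beta = p.beta0 + p.beta1 * f + p.beta2 * f;
  double Gam  = p.G1 * f + p.G2 * f;
  double vpr = V - s.Td / p.K_SR;             // polar-region velocity
  double C = (vpr > 0.0) ? p.C_L : p.C_S;
  double sgn = (vpr > 0.0) ? 1.0 : -1.0;
  double term = C * beta * sgn * std::pow(std::fabs(vpr), p.a_pow)
                * (L - p.L0_SR - s.T / p.K_SR - p.R);
  dT = s.Td;
  dTd = p.K_SR / p.M * (term
        + p.K_PR * (L - p.L0_SR - s.T / p.K_SR - p.L0_PR)
        + p.M * A + Gam - s.T);
}

static inline void intrafusal_rk4(IntrafusalState& s, double gamma,
                                  double L, double V, double A,
                                  const IntrafusalPar& p, double h) {
  double df1, dT1, dTd1, df2, dT2, dTd2, df3, dT3, dTd3, df4, dT4, dTd4;
  IntrafusalState t = s;
  intrafusal_deriv(t, gamma, L, V, A, p, df1, dT1, dTd1);
  t.f = s.f + 0.5 * h * df1; t.T = s.T + 0.5 * h * dT1; t.Td = s.Td + 0.5 * h * dTd1;
  intrafusal_deriv(t, gamma, L, V, A, p, df2, dT2, dTd2);
  t.f = s.f + 0.5 * h * df2; t.T = s.T + 0.5 * h * dT2; t.Td = s.Td + 0.5 * h * dTd2;
  intrafusal_deriv(t, gamma, L, V, A, p, df3, dT3, dTd3);
  t.f = s.f + h * df3; t.T = s.T + h * dT3; t.Td = s.Td + h * dTd3;
  intrafusal_deriv(t, gamma, L, V, A, p, df4, dT4, dTd4);
  s.f += h / 6.0 * (df1 + 2 * df2 + 2 * df3 + df4);
  s.T += h / 6.0 * (dT1 + 2 * dT2 + 2 * dT3 + dT4);
  s.Td += h / 6.0 * (dTd1 + 2 * dTd2 + 2 * dTd3 + dTd4);
  if (p.tau <= 1e-3) {
    double gp = std::pow(gamma, p.p);
    s.f = gp / (gp + std::pow(p.freq, p.p));
  }
}

static inline double intrafusal_primary(const IntrafusalState& s,
                                        const IntrafusalPar& p, double gain) {
  double v = gain * p.Gpri * (s.T / p.K_SR - (p.LN_SR - p.L0_SR));
  return v > 0.0 ? v : 0.0;
}

static inline double intrafusal_secondary(const IntrafusalState& s, double L,
                                          const IntrafusalPar& p, double gain) {
  if (p.Gsec <= 0.0) return 0.0;
  double v = gain * p.Gsec * (p.X * (p.L_sec / p.L0_SR) * (s.T / p.K_SR - (p.LN_SR - p.L0_SR))
            + (1.0 - p.X) * (p.L_sec / p.L0_PR) * (L - s.T / p.K_SR - p.L0_SR - p.LN_PR));
  return v > 0.0 ? v : 0.0;
}

struct SpindleState {
  IntrafusalState b1, b2, ch;
  double prevV;
};

struct SpindlePar {
  IntrafusalPar b1, b2, ch;
  double g1, g2, g3;   // afferent-potential gain multipliers
  double S_occl;
};

static inline void spindle_init(SpindleState& s, const SpindlePar& sp,
                                double L, double gs, double gd) {
  const IntrafusalPar* ps[3] = { &sp.b1, &sp.b2, &sp.ch };
  IntrafusalState* ss[3] = { &s.b1, &s.b2, &s.ch };
  double gam[3] = { gd, gs, gs };
  for (int i = 0; i < 3; ++i) {
    const IntrafusalPar& p = *ps[i];
    double gp = std::pow(gam[i], p.p);
    double f = gp / (gp + std::pow(p.freq, p.p));
    double Gam = p.G1 * f + p.G2 * f;
    double T = (p.K_PR * (L - p.L0_SR - p.L0_PR) + Gam) / (1.0 + p.K_PR / p.K_SR);
    ss[i]->f = f; ss[i]->T = T; ss[i]->Td = 0.0;
  }
  s.prevV = 0.0;
}

static inline void spindle_step(SpindleState& s, const SpindlePar& sp,
                                double L, double V, double A,
                                double gs, double gd, double h,
                                double& Ia, double& II) {
  intrafusal_rk4(s.b1, gd, L, V, A, sp.b1, h);
  intrafusal_rk4(s.b2, gs, L, V, A, sp.b2, h);
  intrafusal_rk4(s.ch, gs, L, V, A, sp.ch, h);
  double p1 = intrafusal_primary(s.b1, sp.b1, sp.g1);
  double p23 = intrafusal_primary(s.b2, sp.b2, sp.g2)
             + intrafusal_primary(s.ch, sp.ch, sp.g3);
  double hi = p1 > p23 ? p1 : p23, lo = p1 > p23 ? p23 : p1;
  Ia = hi + sp.S_occl * lo;
  II = intrafusal_secondary(s.b2, L, sp.b2, sp.g2)
     + intrafusal_secondary(s.ch, L, sp.ch, sp.g3);
}

// ---------------------------------------------------------------------------
// Golgi tendon organ: static log nonlinearity + Houk-type dynamics as three
// bilinear first-order sections (zeros 0.15, 1.5, 16; poles 0.2, 2, 37 rad/s),
// DC gain normalised to 1.
// ---------------------------------------------------------------------------

struct GTOFilter {
  double b0[3], b1[3], a1[3];
  double xm[3], ym[3];
  double gain;
  void design(double fs) {
    const double z[3] = { 0.15, 1.5, 16.0 }, p[3] = { 0.2, 2.0, 37.0 };
    double K = 2.0 * fs;
    double dc = 1.0;
    for (int i = 0; i < 3; ++i) {
      b0[i] = (K + z[i]) / (K + p[i]);
      b1[i] = (z[i] - K) / (K + p[i]);
      a1[i] = (p[i] - K) / (K + p[i]);
      dc *= z[i] / p[i];
      xm[i] = ym[i] = 0.0;
    }
    gain = 1.0 / dc;
  }
  void init_steady(double u) {
    double x = u;
    for (int i = 0; i < 3; ++i) {
      double y = x * (b0[i] + b1[i]) / (1.0 + a1[i]);
      xm[i] = x; ym[i] = y; x = y;
    }
  }
  double step(double u) {
    double x = u;
    for (int i = 0; i < 3; ++i) {
      double y = b0[i] * x + b1[i] * xm[i] - a1[i] * ym[i];
      xm[i] = x; ym[i] = y; x = y;
    }
    return gain * x;
  }
};

static inline double gto_static(double F_share, double g1, double g2) {
  return F_share <= 0.0 ? 0.0 : g1 * std::log1p(F_share / g2);
}

// ---------------------------------------------------------------------------
// Neurons: two-compartment (soma+dendrite) conductance-based model with
// stereotyped spike conductance transients and a saturating AHP conductance.
// ---------------------------------------------------------------------------

struct NeuronPool {
  int n;
  std::vector<double> Cs, Cd, gls, gld, gc, thr, gNa, gKf, gKs, tau_q;
  std::vector<int> two_comp;
  // state
  std::vector<double> Vs, Vd, q;
  std::vector<double> t_spike;       // last spike time (ms), -inf if none
  // precomputed q decay per half step and inverse capacitances
  std::vector<double> qdec_h, iCs, iCd;
  double tau_na_ms = 0.2, na_win_ms = 0.6, tau_kf_ms = 0.5, kf_win_ms = 4.0;
  double refrac_ms = 2.0, q_jump = 0.35;

  void init() {
    Vs.assign(n, 0.0); Vd.assign(n, 0.0); q.assign(n, 0.0);
    t_spike.assign(n, -1e9);
  }
  void precompute(double dt_ms) {
    qdec_h.resize(n); iCs.resize(n); iCd.resize(n);
    for (int i = 0; i < n; ++i) {
      qdec_h[i] = std::exp(-0.5 * dt_ms / tau_q[i]);
      iCs[i] = 1.0 / Cs[i];
      iCd[i] = 1.0 / Cd[i];
    }
  }
  inline double m_gate(int i, double t_ms) const {
    double d = t_ms - t_spike[i];
    return (d >= 0.0 && d < na_win_ms) ? std::exp(-d / tau_na_ms) : 0.0;
  }
  inline double n_gate(int i, double t_ms) const {
    double d = t_ms - t_spike[i];
    if (d < 0.05 || d >= kf_win_ms) return 0.0;
    double x = d / tau_kf_ms;
    return x * std::exp(1.0 - x);
  }
  // advance one step; gexc/ginh are dendritic (MN) or somatic (IN)
  // conductances in uS, Iinj in nA at the soma; spikes appended as indices
  void step(double t_ms, double dt_ms,
            const std::vector<double>& gexc, const std::vector<double>& ginh,
            const double* Iinj, std::vector<int>& spikes) {
    const double Eexc = 70.0, Einh = -16.0;
    for (int i = 0; i < n; ++i) {
      double vs = Vs[i], vd = Vd[i];
      double q0 = q[i], qh = q0 * qdec_h[i], q1 = qh * qdec_h[i];
      double m0 = m_gate(i, t_ms), mh = m_gate(i, t_ms + 0.5 * dt_ms), m1 = m_gate(i, t_ms + dt_ms);
      double n0 = n_gate(i, t_ms), nh = n_gate(i, t_ms + 0.5 * dt_ms), n1 = n_gate(i, t_ms + dt_ms);
      double ge = gexc[i], gi = ginh[i];
      double k1s, k1d, k2s, k2d, k3s, k3d, k4s, k4d;
      if (two_comp[i]) {
        #define DVS(vs_, vd_, mm, nn, qq) ((-gls[i]*(vs_) - gc[i]*((vs_)-(vd_)) \
           + gNa[i]*(mm)*(E_NA-(vs_)) + gKf[i]*(nn)*(E_K-(vs_)) \
           + gKs[i]*(qq)*(E_K-(vs_)) + Iinj[i]) * iCs[i])
        #define DVD(vs_, vd_) ((-gld[i]*(vd_) - gc[i]*((vd_)-(vs_)) \
           + ge*(Eexc-(vd_)) + gi*(Einh-(vd_))) * iCd[i])
        k1s = DVS(vs, vd, m0, n0, q0); k1d = DVD(vs, vd);
        k2s = DVS(vs + 0.5*dt_ms*k1s, vd + 0.5*dt_ms*k1d, mh, nh, qh);
        k2d = DVD(vs + 0.5*dt_ms*k1s, vd + 0.5*dt_ms*k1d);
        k3s = DVS(vs + 0.5*dt_ms*k2s, vd + 0.5*dt_ms*k2d, mh, nh, qh);
        k3d = DVD(vs + 0.5*dt_ms*k2s, vd + 0.5*dt_ms*k2d);
        k4s = DVS(vs + dt_ms*k3s, vd + dt_ms*k3d, m1, n1, q1);
        k4d = DVD(vs + dt_ms*k3s, vd + dt_ms*k3d);
        #undef DVS
        #undef DVD
        Vd[i] = vd + dt_ms / 6.0 * (k1d + 2*k2d + 2*k3d + k4d);
      } else {
        #define DVS1(vs_, mm, nn, qq) ((-gls[i]*(vs_) \
           + gNa[i]*(mm)*(E_NA-(vs_)) + gKf[i]*(nn)*(E_K-(vs_)) \
           + gKs[i]*(qq)*(E_K-(vs_)) + ge*(Eexc-(vs_)) + gi*(Einh-(vs_)) \
           + Iinj[i]) * iCs[i])
        k1s = DVS1(vs, m0, n0, q0);
        k2s = DVS1(vs + 0.5*dt_ms*k1s, mh, nh, qh);
        k3s = DVS1(vs + 0.5*dt_ms*k2s, mh, nh, qh);
        k4s = DVS1(vs + dt_ms*k3s, m1, n1, q1);
        #undef DVS1
      }
      double vs1 = vs + dt_ms / 6.0 * (k1s + 2*k2s + 2*k3s + k4s);
      q[i] = q1;
      double tnew = t_ms + dt_ms;
      if (vs1 >= thr[i] && vs < thr[i] && (tnew - t_spike[i]) > refrac_ms) {
        t_spike[i] = tnew;
        q[i] += q_jump * (1.0 - q[i]);
        spikes.push_back(i);
      }
      Vs[i] = vs1;
    }
  }
};

// ---------------------------------------------------------------------------
// Lumped saturating synapse banks (two-state kinetic scheme, per-target
// aggregation over identical synapses of one projection class).
// ---------------------------------------------------------------------------

struct Projection {
  // CSR over sources
  std::vector<int> ptr, tgt;       // tgt: global neuron index
  std::vector<int> delay_steps;    // per source
  int tgt_lo, tgt_hi;              // targets fall in [tgt_lo, tgt_hi)
  double ghat;                     // per-synapse conductance, uS
  bool inhib, to_dend;
  double alpha, beta;              // 1/ms (alpha at T = 1 mM)
  int Tdur_steps;
  // lumped state per target (offset by tgt_lo)
  std::vector<double> S_on, S_off;
  std::vector<int> N_on;
  double e_off, e_on, s_inf;
  void prep(double dt_ms) {
    int m = tgt_hi - tgt_lo;
    S_on.assign(m, 0.0); S_off.assign(m, 0.0); N_on.assign(m, 0);
    e_off = std::exp(-beta * dt_ms);
    double lam = alpha + beta;
    s_inf = alpha / lam;
    e_on = std::exp(-lam * dt_ms);
  }
  inline void advance() {
    int m = tgt_hi - tgt_lo;
    for (int j = 0; j < m; ++j) {
      S_off[j] *= e_off;
      double target = N_on[j] * s_inf;
      S_on[j] = target + (S_on[j] - target) * e_on;
    }
  }
  inline void pulse_on(int t) {
    int j = t - tgt_lo;
    // transfer the (approximate, group-mean) state of one synapse on->off
    // bookkeeping is exact for homogeneous groups
    S_on[j] += 0.0;
    N_on[j] += 1;
  }
  inline void pulse_off(int t) {
    int j = t - tgt_lo;
    if (N_on[j] > 0) {
      double m = S_on[j] / N_on[j];
      S_on[j] -= m; S_off[j] += m; N_on[j] -= 1;
    }
  }
  inline void accumulate(std::vector<double>& gexc_d, std::vector<double>& ginh_d,
                         std::vector<double>& gexc_s, std::vector<double>& ginh_s) const {
    std::vector<double>& dst = to_dend ? (inhib ? ginh_d : gexc_d)
                                       : (inhib ? ginh_s : gexc_s);
    int m = tgt_hi - tgt_lo;
    for (int j = 0; j < m; ++j) {
      double s = S_on[j] + S_off[j];
      if (s > 0.0) dst[tgt_lo + j] += ghat * s;
    }
  }
  // single-pass kinetic update + conductance accumulation
  inline void advance_accumulate(std::vector<double>& gexc_d,
                                 std::vector<double>& ginh_d,
                                 std::vector<double>& gexc_s,
                                 std::vector<double>& ginh_s) {
    std::vector<double>& dst = to_dend ? (inhib ? ginh_d : gexc_d)
                                       : (inhib ? ginh_s : gexc_s);
    int m = tgt_hi - tgt_lo;
    double* so = S_on.data();
    double* sf = S_off.data();
    const int* no = N_on.data();
    double* d = dst.data() + tgt_lo;
    for (int j = 0; j < m; ++j) {
      sf[j] *= e_off;
      double target = no[j] * s_inf;
      so[j] = target + (so[j] - target) * e_on;
      double s = so[j] + sf[j];
      if (s > 0.0) d[j] += ghat * s;
    }
  }
};

struct SynEvent { int proj, tgt, sign; };


// List -> struct converters
static inline MTUPar mtu_from_list(const List& p) {
  MTUPar m;
  m.F0 = as<double>(p["F0_N"]);
  m.L0_m = as<double>(p["L0_cm"]) / 100.0;
  m.mass = as<double>(p["mass_kg"]);
  m.k_pe = as<double>(p["k_pe"]);
  m.b_pe = as<double>(p["b_pe"]);
  m.strain = as<double>(p["strain"]);
  m.sin_a0 = std::sin(as<double>(p["alpha0_deg"]) * M_PI / 180.0);
  m.Lt1_m = as<double>(p["Lt1_cm"]) / 100.0;
  m.c_t = as<double>(p["c_t"]);
  m.k_t = as<double>(p["k_t"]);
  m.L_r = as<double>(p["L_r"]);
  for (int i = 0; i < 5; ++i) { m.a[i] = 0.0; m.b[i] = 0.0; }
  if (p.containsElementNamed("a")) {
    NumericVector a = p["a"], b = p["b"];
    for (int i = 0; i < 5; ++i) { m.a[i] = a[i]; m.b[i] = b[i]; }
  }
  return m;
}

static inline FibreCurve curve_from_list(const List& p) {
  FibreCurve c;
  c.beta = as<double>(p["fl_beta"]); c.omega = as<double>(p["fl_omega"]);
  c.rho = as<double>(p["fl_rho"]); c.vmax = as<double>(p["fv_vmax"]);
  c.cv0 = as<double>(p["fv_cv0"]); c.cv1 = as<double>(p["fv_cv1"]);
  c.av0 = as<double>(p["fv_av0"]); c.av1 = as<double>(p["fv_av1"]);
  c.av2 = as<double>(p["fv_av2"]); c.bv = as<double>(p["fv_bv"]);
  return c;
}

static inline SpindlePar spindle_from_list(const List& sp) {
  SpindlePar s;
  List fibres = sp["fibres"];
  CharacterVector nm = CharacterVector::create("bag1", "bag2", "chain");
  IntrafusalPar* dst[3] = { &s.b1, &s.b2, &s.ch };
  for (int i = 0; i < 3; ++i) {
    List f = fibres[std::string(nm[i])];
    IntrafusalPar& p = *dst[i];
    p.tau = as<double>(f["tau"]); p.freq = as<double>(f["freq"]);
    p.p = as<double>(f["p"]); p.beta0 = as<double>(f["beta0"]);
    p.beta1 = as<double>(f["beta1"]); p.beta2 = as<double>(f["beta2"]);
    p.G1 = as<double>(f["Gamma1"]); p.G2 = as<double>(f["Gamma2"]);
    p.C_L = as<double>(f["C_L"]); p.C_S = as<double>(f["C_S"]);
    p.K_SR = as<double>(f["K_SR"]); p.K_PR = as<double>(f["K_PR"]);
    p.M = as<double>(f["M"]); p.L0_SR = as<double>(f["L0_SR"]);
    p.L0_PR = as<double>(f["L0_PR"]); p.LN_SR = as<double>(f["LN_SR"]);
    p.LN_PR = as<double>(f["LN_PR"]); p.R = as<double>(f["R"]);
    p.a_pow = as<double>(f["a_pow"]); p.Gpri = as<double>(f["G_pri"]);
    p.Gsec = as<double>(f["G_sec"]); p.X = as<double>(f["X"]);
    p.L_sec = as<double>(f["L_sec"]);
  }
  NumericVector g = sp["gains"];
  s.g1 = g[0]; s.g2 = g[1]; s.g3 = g[2];
  s.S_occl = as<double>(sp["S_occl"]);
  return s;
}

#endif // NMSTAND_CORE_H
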