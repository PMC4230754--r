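#include "core.h"
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Exported component traces (unit-test surface)
// ---------------------------------------------------------------------------





// [[Rcpp::export(name = ".tendon_force_cpp")]]
NumericVector tendon_force_cpp(NumericVector Lt, double c_t, double k_t, double L_r) {
  NumericVector out(Lt.size());
  for (R_xlen_t i = 0; i < Lt.size(); ++i)
    out[i] = tendon_force_norm(Lt[i], c_t, k_t, L_r);
  return out;
}

// [[Rcpp::export(name = ".pe_force_cpp")]]
NumericVector pe_force_cpp(NumericVector L, NumericVector V, List mtu) {
  MTUPar p = mtu_from_list(mtu);
  NumericVector out(L.size());
  for (R_xlen_t i = 0; i < L.size(); ++i)
    out[i] = pe_elastic(L[i], p) + p.b_pe * V[i];
  return out;
}

// [[Rcpp::export(name = ".flfv_cpp")]]
NumericVector flfv_cpp(NumericVector L, NumericVector V, List curve, bool fl_only) {
  FibreCurve c = curve_from_list(curve);
  NumericVector out(L.size());
  for (R_xlen_t i = 0; i < L.size(); ++i)
    out[i] = fl_only ? fl_curve(L[i], c) : fl_curve(L[i], c) * fv_curve(L[i], V[i], c);
  return out;
}

// Imposed-length fibre dynamics trace (open-loop musculotendon unit)
// [[Rcpp::export(name = ".mtu_trace_cpp")]]
List mtu_trace_cpp(NumericVector Lmtu_m, NumericVector a_slow, NumericVector a_fast,
                   List mtu, List curve_slow, List curve_fast,
                   double L0state, double dt) {
  MTUPar p = mtu_from_list(mtu);
  FibreCurve cs = curve_from_list(curve_slow), cf = curve_from_list(curve_fast);
  int n = Lmtu_m.size();
  NumericVector Lf(n), Vf(n), Ft(n), acc(n);
  double L = L0state, V = 0.0, dV, F;
  for (int i = 0; i < n; ++i) {
    double k1v, k2v, k3v, k4v, F1;
    if (!fibre_deriv(L, V, Lmtu_m[i], a_slow[i], a_fast[i], p, cs, cf, k1v, F1))
      stop("pinnation geometry impossible (sin(alpha) >= 1) at step %d", i);
    double k1l = V;
    double L2 = L + 0.5 * dt * k1l, V2 = V + 0.5 * dt * k1v;
    fibre_deriv(L2, V2, Lmtu_m[i], a_slow[i], a_fast[i], p, cs, cf, k2v, F);
    double k2l = V2;
    double L3 = L + 0.5 * dt * k2l, V3 = V + 0.5 * dt * k2v;
    fibre_deriv(L3, V3, Lmtu_m[i], a_slow[i], a_fast[i], p, cs, cf, k3v, F);
    double k3l = V3;
    double L4 = L + dt * k3l, V4 = V + dt * k3v;
    fibre_deriv(L4, V4, Lmtu_m[i], a_slow[i], a_fast[i], p, cs, cf, k4v, F);
    double k4l = V4;
    Lf[i] = L; Vf[i] = V; Ft[i] = F1 * p.F0; acc[i] = k1v;
    L += dt / 6.0 * (k1l + 2*k2l + 2*k3l + k4l);
    V += dt / 6.0 * (k1v + 2*k2v + 2*k3v + k4v);
    if (!std::isfinite(L) || !std::isfinite(V))
      stop("fibre state diverged at step %d", i);
  }
  return List::create(_["L_f"] = Lf, _["V_f"] = Vf, _["F_tendon"] = Ft, _["accel"] = acc);
}

// passive static fibre equilibrium (activation optionally fixed)
// [[Rcpp::export(name = ".fibre_equilibrium_cpp")]]
double fibre_equilibrium_cpp(double Lmtu_m, double a_slow, double a_fast,
                             List mtu, List curve_slow, List curve_fast) {
  MTUPar p = mtu_from_list(mtu);
  FibreCurve cs = curve_from_list(curve_slow), cf = curve_from_list(curve_fast);
  double lo = std::max(0.30, p.sin_a0 + 1e-3), hi = 1.8;
  auto h = [&](double L) {
    double sin_a, cos_a;
    pinnation(L, p, sin_a, cos_a);
    double Lt = (Lmtu_m - L * p.L0_m * cos_a) / p.Lt1_m;
    double Ft = tendon_force_norm(Lt, p.c_t, p.k_t, p.L_r);
    double Ff = pe_elastic(L, p)
              + a_slow * fl_curve(L, cs) * fv_curve(L, 0.0, cs)
              + a_fast * fl_curve(L, cf) * fv_curve(L, 0.0, cf);
    return Ft - cos_a * Ff;
  };
  double flo = h(lo), fhi = h(hi);
  if (flo * fhi > 0.0) return flo > 0.0 ? hi : lo;
  for (int it = 0; it < 80; ++it) {
    double mid = 0.5 * (lo + hi), fm = h(mid);
    if (flo * fm <= 0.0) { hi = mid; fhi = fm; } else { lo = mid; flo = fm; }
  }
  return 0.5 * (lo + hi);
}



// [[Rcpp::export(name = ".spindle_trace_cpp")]]
List spindle_trace_cpp(NumericVector L, NumericVector gamma_s, NumericVector gamma_d,
                       List spindle, double dt) {
  SpindlePar sp = spindle_from_list(spindle);
  int n = L.size();
  SpindleState st;
  spindle_init(st, sp, L[0], gamma_s[0], gamma_d[0]);
  NumericVector Ia(n), II(n);
  double prevL = L[0], prevV = 0.0;
  for (int i = 0; i < n; ++i) {
    double V = (i == 0) ? 0.0 : (L[i] - prevL) / dt;
    double A = (V - prevV) / dt;
    prevL = L[i]; prevV = V;
    double ia, ii;
    spindle_step(st, sp, L[i], V, A, gamma_s[i], gamma_d[i], dt, ia, ii);
    Ia[i] = ia; II[i] = ii;
    if (!std::isfinite(ia)) stop("spindle state diverged at step %d", i);
  }
  return List::create(_["Ia"] = Ia, _["II"] = II);
}

// [[Rcpp::export(name = ".gto_trace_cpp")]]
NumericVector gto_trace_cpp(NumericVector F_share, double fs, double g1, double g2) {
  GTOFilter f;
  f.design(fs);
  f.init_steady(gto_static(F_share[0], g1, g2));
  NumericVector out(F_share.size());
  for (R_xlen_t i = 0; i < F_share.size(); ++i) {
    double v = f.step(gto_static(F_share[i], g1, g2));
    out[i] = v > 0.0 ? v : 0.0;
  }
  return out;
}

// Single pool of neurons driven by injected soma current (no synapses)
// [[Rcpp::export(name = ".neuron_trace_cpp")]]
List neuron_trace_cpp(List pars, NumericMatrix Iinj, double dt_s) {
  NeuronPool pool;
  pool.n = as<int>(pars["n"]);
  pool.Cs = as<std::vector<double>>(pars["Cs"]);
  pool.Cd = as<std::vector<double>>(pars["Cd"]);
  pool.gls = as<std::vector<double>>(pars["gls"]);
  pool.gld = as<std::vector<double>>(pars["gld"]);
  pool.gc = as<std::vector<double>>(pars["gc"]);
  pool.thr = as<std::vector<double>>(pars["thr"]);
  pool.gNa = as<std::vector<double>>(pars["gNa"]);
  pool.gKf = as<std::vector<double>>(pars["gKf"]);
  pool.gKs = as<std::vector<double>>(pars["gKs"]);
  pool.tau_q = as<std::vector<double>>(pars["tau_q"]);
  pool.two_comp = as<std::vector<int>>(pars["two_comp"]);
  pool.init();
  double dt_ms = dt_s * 1000.0;
  pool.precompute(dt_ms);
  int nstep = Iinj.nrow();
  std::vector<double> gz(pool.n, 0.0);
  std::vector<double> Icur(pool.n);
  NumericMatrix V(nstep, pool.n);
  std::vector<double> sp_t; std::vector<int> sp_id;
  std::vector<int> spikes;
  for (int i = 0; i < nstep; ++i) {
    for (int j = 0; j < pool.n; ++j) Icur[j] = Iinj(i, j);
    spikes.clear();
    pool.step(i * dt_ms, dt_ms, gz, gz, Icur.data(), spikes);
    for (int s : spikes) { sp_t.push_back((i + 1) * dt_s); sp_id.push_back(s + 1); }
    for (int j = 0; j < pool.n; ++j) V(i, j) = pool.Vs[j];
    if (!std::isfinite(pool.Vs[0])) stop("membrane potential diverged at step %d", i);
  }
  return List::create(_["V"] = V,
                      _["spike_t"] = wrap(sp_t), _["spike_id"] = wrap(sp_id));
}

// Lumped synapse bank driven by a presynaptic spike train (single target)
// [[Rcpp::export(name = ".synapse_trace_cpp")]]
NumericVector synapse_trace_cpp(NumericVector spike_t, int n_syn, double ghat,
                                double alpha, double beta, double Tdur_ms,
                                double dt_s, double duration_s) {
  double dt_ms = dt_s * 1000.0;
  int nstep = (int)std::llround(duration_s / dt_s);
  int Tdur_steps = std::max(1, (int)std::llround(Tdur_ms / dt_ms));
  Projection p;
  p.tgt_lo = 0; p.tgt_hi = 1;
  p.alpha = alpha; p.beta = beta; p.Tdur_steps = Tdur_steps;
  p.ghat = ghat;
  p.prep(dt_ms);
  // each presynaptic spike drives every one of the n_syn synapses
  std::vector<std::vector<int>> ev(nstep + Tdur_steps + 2);
  for (R_xlen_t k = 0; k < spike_t.size(); ++k) {
    int s = (int)std::llround(spike_t[k] / dt_s);
    if (s < 0) stop("presynaptic event earlier than current time");
    if (s >= nstep) continue;
    ev[s].push_back(+n_syn);
    ev[s + Tdur_steps].push_back(-n_syn);
  }
  NumericVector g(nstep);
  for (int i = 0; i < nstep; ++i) {
    for (int e : ev[i]) {
      int cnt = std::abs(e);
      for (int r = 0; r < cnt; ++r) { if (e > 0) p.pulse_on(0); else p.pulse_off(0); }
    }
    p.advance();
    g[i] = p.ghat * (p.S_on[0] + p.S_off[0]);
  }
  return g;
}

// Homogeneous gamma renewal spike train
// [[Rcpp::export(name = ".gamma_train_cpp")]]
NumericVector gamma_train_cpp(double rate, double shape, double duration, int seed) {
  std::mt19937_64 rng(seed);
  std::gamma_distribution<double> gd(shape, 1.0 / (rate * shape));
  std::vector<double> t;
  double cur = gd(rng);   // start from an ordinary renewal process origin
  while (cur < duration) { t.push_back(cur); cur += gd(rng); }
  return wrap(t);
}

// Non-homogeneous gamma encoder by time rescaling
// [[Rcpp::export(name = ".encode_gamma_cpp")]]
NumericVector encode_gamma_cpp(NumericVector rate, double dt, double order, int seed) {
  std::mt19937_64 rng(seed);
  std::gamma_distribution<double> gd(order, 1.0 / order);
  std::vector<double> t;
  double Lam = 0.0, next = gd(rng);
  for (R_xlen_t i = 0; i < rate.size(); ++i) {
    Lam += rate[i] * dt;
    while (Lam >= next) {
      t.push_back((i + 1) * dt);
      next += gd(rng);
    }
  }
  return wrap(t);
}

// Inverted pendulum trace under an imposed muscle-torque series
// [[Rcpp::export(name = ".pendulum_trace_cpp")]]
List pendulum_trace_cpp(NumericVector Tm, double m, double h, double g,
                        double K_pas, double B_pas, double theta0, double omega0,
                        double dt, double fall_rad, double theta_ref) {
  double I = m * h * h;
  int n = Tm.size();
  NumericVector theta(n), omega(n), Ta(n);
  double th = theta0, om = omega0;
  int fell_at = -1;
  for (int i = 0; i < n; ++i) {
    theta[i] = th; omega[i] = om;
    Ta[i] = K_pas * (th - theta_ref) + B_pas * om - Tm[i];
    auto acc = [&](double th_, double om_) {
      return (m * g * h * std::sin(th_) + Tm[i] - K_pas * (th_ - theta_ref) - B_pas * om_) / I;
    };
    double k1t = om, k1w = acc(th, om);
    double k2t = om + 0.5 * dt * k1w, k2w = acc(th + 0.5 * dt * k1t, om + 0.5 * dt * k1w);
    double k3t = om + 0.5 * dt * k2w, k3w = acc(th + 0.5 * dt * k2t, om + 0.5 * dt * k2w);
    double k4t = om + dt * k3w, k4w = acc(th + dt * k3t, om + dt * k3w);
    th += dt / 6.0 * (k1t + 2*k2t + 2*k3t + k4t);
    om += dt / 6.0 * (k1w + 2*k2w + 2*k3w + k4w);
    if (fell_at < 0 && std::fabs(th) > fall_rad) { fell_at = i; break; }
  }
  return List::create(_["theta"] = theta, _["omega"] = omega, _["T_a"] = Ta,
                      _["fell_at"] = fell_at);
}
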