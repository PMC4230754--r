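// Closed-loop simulation engine: advances spinal pools, musculotendon units,
// proprioceptors, afferent encoders and the inverted pendulum on a single
// fixed-step RK4 clock (default 50 us).

#include "core.h"
using namespace Rcpp;

enum Mode { CLOSED = 0, LOCKED = 1, IMPOSED = 2, FIXED_ACT = 3 };

struct MuImpulse { int neuron; };

// [[Rcpp::export(name = ".run_engine_cpp")]]
List run_engine_cpp(int mode, double dt, double duration_s, double lock_s,
                    double theta0, double fall_rad,
                    List body, List muscles, List curves, List spindle, List gto,
                    Nullable<List> neurons_, List projections, List descending,
                    Nullable<List> afferents_, List fusimotor,
                    bool feedback_on, bool controller_on,
                    Nullable<NumericMatrix> fixed_a_,
                    Nullable<NumericVector> imposed_theta_,
                    int seed_encode, int seed_fusimotor,
                    int decim, bool record_spikes) {
  const int nstep = (int)std::llround(duration_s / dt);
  const double dt_ms = dt * 1000.0;
  const int lock_steps = (int)std::llround(lock_s / dt);

  // body
  const double m_b = as<double>(body["m"]), h_b = as<double>(body["h"]),
               g_b = as<double>(body["g"]), K_pas = as<double>(body["K_pas"]),
               B_pas = as<double>(body["B_pas"]);
  const double th_ref = body.containsElementNamed("theta_ref")
                        ? as<double>(body["theta_ref"]) : 0.0;
  const double I_b = m_b * h_b * h_b;

  // muscles
  const int NM = muscles.size();
  std::vector<MTUPar> mtu(NM);
  std::vector<double> Lf(NM), Vf(NM), accel(NM, 0.0), Ft_norm(NM, 0.0);
  std::vector<double> sp_off(NM, 0.0);   // spindle mounting offset (L0 units)
  for (int k = 0; k < NM; ++k) {
    List mk = muscles[k];
    mtu[k] = mtu_from_list(mk);
    Lf[k] = as<double>(mk["L_init"]);
    if (mk.containsElementNamed("spindle_offset"))
      sp_off[k] = as<double>(mk["spindle_offset"]);
    Vf[k] = 0.0;
  }
  FibreCurve cs = curve_from_list(curves["slow"]), cf = curve_from_list(curves["fast"]);

  // spindles + GTO
  SpindlePar spp = spindle_from_list(spindle);
  std::vector<SpindleState> spst(NM);
  const double gto_g1 = as<double>(gto["g1"]), gto_g2 = as<double>(gto["g2"]);
  NumericVector gto_nib = gto["n_ib"];
  std::vector<GTOFilter> gtof(NM);

  // fusimotor OU processes (per muscle, static & dynamic)
  const double fus_ms = as<double>(fusimotor["mean_s"]),
               fus_md = as<double>(fusimotor["mean_d"]),
               fus_var_frac = as<double>(fusimotor["var_frac"]),
               fus_tau = as<double>(fusimotor["tau"]);
  std::mt19937_64 rng_fus((unsigned)seed_fusimotor);
  std::normal_distribution<double> nrm(0.0, 1.0);
  std::vector<double> gam_s(NM, fus_ms), gam_d(NM, fus_md);
  const double sd_s = std::sqrt(fus_var_frac * fus_ms),
               sd_d = std::sqrt(fus_var_frac * fus_md);
  const double ou_a = dt / fus_tau, ou_b = std::sqrt(2.0 * dt / fus_tau);

  for (int k = 0; k < NM; ++k) {
    spindle_init(spst[k], spp, Lf[k] + sp_off[k], fus_ms, fus_md);
    gtof[k].design(1.0 / dt);
    gtof[k].init_steady(0.0);
  }

  // neurons
  NeuronPool pool;
  std::vector<int> is_mn, nrn_muscle, mu_slow, axon_delay;
  std::vector<double> tc, c_sat, A_tet, emg_amp, emg_lam;
  bool have_neurons = controller_on && neurons_.isNotNull();
  if (have_neurons) {
    List nn(neurons_);
    pool.n = as<int>(nn["n"]);
    pool.Cs = as<std::vector<double>>(nn["Cs"]);
    pool.Cd = as<std::vector<double>>(nn["Cd"]);
    pool.gls = as<std::vector<double>>(nn["gls"]);
    pool.gld = as<std::vector<double>>(nn["gld"]);
    pool.gc = as<std::vector<double>>(nn["gc"]);
    pool.thr = as<std::vector<double>>(nn["thr"]);
    pool.gNa = as<std::vector<double>>(nn["gNa"]);
    pool.gKf = as<std::vector<double>>(nn["gKf"]);
    pool.gKs = as<std::vector<double>>(nn["gKs"]);
    pool.tau_q = as<std::vector<double>>(nn["tau_q"]);
    pool.two_comp = as<std::vector<int>>(nn["two_comp"]);
    is_mn = as<std::vector<int>>(nn["is_mn"]);
    nrn_muscle = as<std::vector<int>>(nn["muscle"]);
    mu_slow = as<std::vector<int>>(nn["mu_slow"]);
    axon_delay = as<std::vector<int>>(nn["axon_delay_steps"]);
    tc = as<std::vector<double>>(nn["tc"]);
    c_sat = as<std::vector<double>>(nn["c_sat"]);
    A_tet = as<std::vector<double>>(nn["A_tet"]);
    emg_amp = as<std::vector<double>>(nn["emg_amp"]);
    emg_lam = as<std::vector<double>>(nn["emg_lambda_ms"]);
    pool.init();
    pool.precompute(dt_ms);
  } else {
    pool.n = 0;
  }
  NumericVector act_norm;
  if (Rf_isNull(muscles.attr("act_norm"))) act_norm = NumericVector(NM, 1.0);
  else act_norm = as<NumericVector>(muscles.attr("act_norm"));

  // activation filter states
  std::vector<double> fx1(pool.n, 0.0), fx2(pool.n, 0.0), fe1(pool.n), fdt(pool.n);
  for (int i = 0; i < pool.n; ++i) {
    fe1[i] = std::exp(-dt / (tc.empty() ? 1.0 : tc[i]));
    fdt[i] = dt / (tc.empty() ? 1.0 : tc[i]);
  }

  // projections
  int NP = projections.size();
  std::vector<Projection> proj(NP);
  std::vector<int> src_kind(NP), n_src(NP);
  int max_delay = 1;
  for (int p = 0; p < NP; ++p) {
    List lp = projections[p];
    Projection& P = proj[p];
    P.ptr = as<std::vector<int>>(lp["ptr"]);
    P.tgt = as<std::vector<int>>(lp["tgt"]);
    P.delay_steps = as<std::vector<int>>(lp["delay_steps"]);
    P.tgt_lo = as<int>(lp["tgt_lo"]); P.tgt_hi = as<int>(lp["tgt_hi"]);
    P.ghat = as<double>(lp["ghat"]);
    P.inhib = as<bool>(lp["inhib"]); P.to_dend = as<bool>(lp["to_dend"]);
    P.alpha = as<double>(lp["alpha"]); P.beta = as<double>(lp["beta"]);
    P.Tdur_steps = as<int>(lp["Tdur_steps"]);
    P.prep(dt_ms);
    src_kind[p] = as<int>(lp["src_kind"]);
    n_src[p] = (int)P.ptr.size() - 1;
    for (int s = 0; s < n_src[p]; ++s)
      if (P.ptr[s + 1] > P.ptr[s])
        max_delay = std::max(max_delay, P.delay_steps[s] + P.Tdur_steps);
  }
  for (size_t i = 0; i < axon_delay.size(); ++i)
    max_delay = std::max(max_delay, axon_delay[i]);
  const int H = max_delay + 4;
  std::vector<std::vector<SynEvent>> ring(H);
  std::vector<std::vector<int>> mu_ring(H);

  auto schedule_spike = [&](int kind, int src, int step_now) {
    for (int p = 0; p < NP; ++p) {
      if (src_kind[p] != kind) continue;
      Projection& P = proj[p];
      if (src >= n_src[p]) continue;
      int a = P.ptr[src], b = P.ptr[src + 1];
      if (a == b) continue;
      int d = std::max(1, P.delay_steps[src]);
      int on = (step_now + d) % H, off = (step_now + d + P.Tdur_steps) % H;
      for (int e = a; e < b; ++e) {
        ring[on].push_back({p, P.tgt[e], +1});
        ring[off].push_back({p, P.tgt[e], -1});
      }
    }
  };

  // descending drive events (pregenerated in R)
  std::vector<int> des_step = as<std::vector<int>>(descending["step"]);
  std::vector<int> des_axon = as<std::vector<int>>(descending["axon"]);
  size_t des_ptr = 0;

  // afferents
  int n_aff = 0;
  std::vector<int> aff_muscle, aff_type, aff_delay;
  std::vector<double> aff_thr, aff_r0, aff_order, aff_Lam, aff_next;
  std::vector<std::mt19937_64> aff_rng;
  bool have_aff = feedback_on && controller_on && afferents_.isNotNull();
  if (have_aff) {
    List af(afferents_);
    n_aff = as<int>(af["n"]);
    aff_muscle = as<std::vector<int>>(af["muscle"]);
    aff_type = as<std::vector<int>>(af["type"]);
    aff_delay = as<std::vector<int>>(af["delay_steps"]);
    aff_thr = as<std::vector<double>>(af["thr"]);
    aff_r0 = as<std::vector<double>>(af["r0"]);
    aff_order = as<std::vector<double>>(af["order"]);
    aff_Lam.assign(n_aff, 0.0);
    aff_next.resize(n_aff);
    aff_rng.reserve(n_aff);
    for (int i = 0; i < n_aff; ++i) {
      aff_rng.emplace_back((unsigned)(seed_encode + 1000003u * (unsigned)(i + 1)));
      std::gamma_distribution<double> gd(aff_order[i], 1.0 / aff_order[i]);
      aff_next[i] = gd(aff_rng[i]);
    }
  }

  // fixed activations (mode FIXED_ACT)
  std::vector<double> fixA_s(NM, 0.0), fixA_f(NM, 0.0);
  if (fixed_a_.isNotNull()) {
    NumericMatrix fa(fixed_a_);
    for (int k = 0; k < NM; ++k) { fixA_s[k] = fa(k, 0); fixA_f[k] = fa(k, 1); }
  }

  NumericVector imposed_theta;
  if (mode == IMPOSED) {
    if (imposed_theta_.isNull()) stop("imposed mode requires a theta trajectory");
    imposed_theta = NumericVector(imposed_theta_);
    if ((int)imposed_theta.size() < nstep) stop("imposed theta shorter than run");
  }

  // recording
  const int nrec = nstep / decim;
  NumericVector rec_t(nrec), rec_th(nrec), rec_om(nrec), rec_Tm(nrec), rec_Ta(nrec),
                rec_xcom(nrec), rec_xcop(nrec);
  NumericMatrix rec_Lf(nrec, NM), rec_Vf(nrec, NM), rec_Ft(nrec, NM),
                rec_as(nrec, NM), rec_af(nrec, NM), rec_Ia(nrec, NM),
                rec_II(nrec, NM), rec_Ib(nrec, NM), rec_emg(nrec, NM);
  std::vector<double> sp_t; std::vector<int> sp_id;      // neuron spikes
  std::vector<double> af_t; std::vector<int> af_id;      // afferent spikes

  // EMG accumulation buffer aligned to recording grid
  std::fill(rec_emg.begin(), rec_emg.end(), 0.0);
  const double dt_rec = dt * decim;
  auto add_muap = [&](int neuron, int arrive_step) {
    int k = nrn_muscle[neuron];
    if (k < 0) return;
    double lam = emg_lam[neuron], A = emg_amp[neuron];
    int s0 = arrive_step / decim;
    int nsmp = (int)std::ceil(3.0 * lam / (dt_rec * 1000.0));
    for (int s = 0; s <= nsmp; ++s) {
      int idx = s0 + s;
      if (idx >= nrec) break;
      double x = (s * dt_rec * 1000.0) / lam;
      rec_emg(idx, k) += A * x * std::exp(-x * x);
    }
  };

  double th = theta0, om = 0.0;
  double Tm = 0.0;
  int fell_at = -1;
  std::vector<double> gexc_d(pool.n, 0.0), ginh_d(pool.n, 0.0),
                      gexc_s(pool.n, 0.0), ginh_s(pool.n, 0.0),
                      Izero(pool.n, 0.0);
  std::vector<int> spikes;
  std::vector<double> Ia_rate(NM, 0.0), II_rate(NM, 0.0), Ib_rate(NM, 0.0);
  std::vector<double> a_slow(NM, 0.0), a_fast(NM, 0.0);
  std::vector<double> prevLm(NM);

  for (int i = 0; i < nstep; ++i) {
    const double t = i * dt;
    const bool locked = (mode == LOCKED || mode == FIXED_ACT) ||
                        (mode == CLOSED && i < lock_steps);
    if (mode == IMPOSED) { double thn = imposed_theta[i];
      om = (i == 0) ? 0.0 : (thn - th) / dt; th = thn; }

    // 1. deliver scheduled synaptic pulses and motor impulses
    int slot = i % H;
    if (have_neurons) {
      for (const SynEvent& e : ring[slot]) {
        if (e.sign > 0) proj[e.proj].pulse_on(e.tgt); else proj[e.proj].pulse_off(e.tgt);
      }
      ring[slot].clear();
      // 2. advance synapse kinetics, accumulate conductances
      std::fill(gexc_d.begin(), gexc_d.end(), 0.0);
      std::fill(ginh_d.begin(), ginh_d.end(), 0.0);
      std::fill(gexc_s.begin(), gexc_s.end(), 0.0);
      std::fill(ginh_s.begin(), ginh_s.end(), 0.0);
      for (int p = 0; p < NP; ++p)
        proj[p].advance_accumulate(gexc_d, ginh_d, gexc_s, ginh_s);
      // single-compartment neurons take their synapses on the soma arrays;
      // two-compartment ones on the dendrite. merge for the pool step:
      for (int j = 0; j < pool.n; ++j) {
        if (!pool.two_comp[j]) { gexc_d[j] = gexc_s[j]; ginh_d[j] = ginh_s[j]; }
      }
      // 3. neuron step
      spikes.clear();
      pool.step(t * 1000.0, dt_ms, gexc_d, ginh_d, Izero.data(), spikes);
      for (int s : spikes) {
        if (record_spikes) { sp_t.push_back((i + 1) * dt); sp_id.push_back(s + 1); }
        schedule_spike(2, s, i);
        if (is_mn[s]) {
          int arr = i + std::max(1, axon_delay[s]);
          if (arr < nstep) { mu_ring[arr % H].push_back(s); add_muap(s, arr); }
        }
      }
      // descending spikes
      while (des_ptr < des_step.size() && des_step[des_ptr] == i) {
        schedule_spike(0, des_axon[des_ptr], i);
        ++des_ptr;
      }
      // 4. motor-unit activation filters
      for (int nrn : mu_ring[slot]) fx1[nrn] += 1.0;
      mu_ring[slot].clear();
      std::fill(a_slow.begin(), a_slow.end(), 0.0);
      std::fill(a_fast.begin(), a_fast.end(), 0.0);
      for (int j = 0; j < pool.n; ++j) {
        if (!is_mn[j]) continue;
        double x1 = fx1[j];
        fx2[j] = fe1[j] * (fx2[j] + fdt[j] * x1);
        fx1[j] = fe1[j] * x1;
        double u = fx2[j];
        if (u > 1e-12) {
          double cu = c_sat[j] * u, s;
          if (cu < 1e-4) s = 0.5 * cu; else { double e = std::exp(-cu); s = (1.0 - e) / (1.0 + e); }
          double a = A_tet[j] * s;
          int k = nrn_muscle[j];
          if (k >= 0) { if (mu_slow[j]) a_slow[k] += a; else a_fast[k] += a; }
        }
      }
      for (int k = 0; k < NM; ++k) { a_slow[k] /= act_norm[k]; a_fast[k] /= act_norm[k]; }
    }
    if (mode == FIXED_ACT) { a_slow = fixA_s; a_fast = fixA_f; }

    // 5. muscle mechanics under current ankle angle
    double th_deg = th * 180.0 / M_PI;
    Tm = 0.0;
    for (int k = 0; k < NM; ++k) {
      double Lmtu = poly4(mtu[k].a, th_deg) / 100.0;     // m
      double r_m  = poly4(mtu[k].b, th_deg) / 100.0;     // m (signed)
      double L = Lf[k], V = Vf[k], dV, F1;
      if (!fibre_deriv(L, V, Lmtu, a_slow[k], a_fast[k], mtu[k], cs, cf, dV, F1))
        stop("muscle %d: pinnation geometry impossible at t=%.3f", k + 1, t);
      accel[k] = dV;
      double k1l = V, k1v = dV, F;
      double L2 = L + 0.5 * dt * k1l, V2 = V + 0.5 * dt * k1v, k2v;
      fibre_deriv(L2, V2, Lmtu, a_slow[k], a_fast[k], mtu[k], cs, cf, k2v, F);
      double k2l = V2;
      double L3 = L + 0.5 * dt * k2l, V3 = V + 0.5 * dt * k2v, k3v;
      fibre_deriv(L3, V3, Lmtu, a_slow[k], a_fast[k], mtu[k], cs, cf, k3v, F);
      double k3l = V3;
      double L4 = L + dt * k3l, V4 = V + dt * k3v, k4v;
      fibre_deriv(L4, V4, Lmtu, a_slow[k], a_fast[k], mtu[k], cs, cf, k4v, F);
      double k4l = V4;
      Lf[k] = L + dt / 6.0 * (k1l + 2*k2l + 2*k3l + k4l);
      Vf[k] = V + dt / 6.0 * (k1v + 2*k2v + 2*k3v + k4v);
      Ft_norm[k] = F1;
      Tm += 2.0 * r_m * F1 * mtu[k].F0;
      prevLm[k] = Lmtu;
    }

    // 6. fusimotor OU + spindles + GTO
    for (int k = 0; k < NM; ++k) {
      if (sd_s > 0.0) gam_s[k] += (fus_ms - gam_s[k]) * ou_a + sd_s * ou_b * nrm(rng_fus);
      if (sd_d > 0.0) gam_d[k] += (fus_md - gam_d[k]) * ou_a + sd_d * ou_b * nrm(rng_fus);
      double gs = gam_s[k] > 0.0 ? gam_s[k] : 0.0, gd = gam_d[k] > 0.0 ? gam_d[k] : 0.0;
      double ia, ii;
      spindle_step(spst[k], spp, Lf[k] + sp_off[k], Vf[k], accel[k], gs, gd, dt, ia, ii);
      Ia_rate[k] = ia; II_rate[k] = ii;
      double Fsh = Ft_norm[k] * mtu[k].F0 / gto_nib[k];
      double ib = gtof[k].step(gto_static(Fsh, gto_g1, gto_g2));
      Ib_rate[k] = ib > 0.0 ? ib : 0.0;
    }

    // 7. afferent encoders
    if (have_aff) {
      for (int a = 0; a < n_aff; ++a) {
        double r;
        int k = aff_muscle[a];
        switch (aff_type[a]) {
          case 0: r = Ia_rate[k]; break;
          case 1: r = II_rate[k]; break;
          default: r = Ib_rate[k];
        }
        double lam = (r >= aff_thr[a]) ? (aff_r0[a] + r - aff_thr[a]) : 0.0;
        if (lam <= 0.0) continue;
        aff_Lam[a] += lam * dt;
        while (aff_Lam[a] >= aff_next[a]) {
          if (record_spikes) { af_t.push_back((i + 1) * dt); af_id.push_back(a + 1); }
          schedule_spike(1, a, i);
          std::gamma_distribution<double> gd(aff_order[a], 1.0 / aff_order[a]);
          aff_next[a] += gd(aff_rng[a]);
        }
      }
    }

    // 8. pendulum
    double Ta = K_pas * (th - th_ref) + B_pas * om - Tm;
    if (mode == CLOSED && !locked) {
      auto acc = [&](double th_, double om_) {
        return (m_b * g_b * h_b * std::sin(th_) + Tm - K_pas * (th_ - th_ref) - B_pas * om_) / I_b;
      };
      double k1t = om, k1w = acc(th, om);
      double k2t = om + 0.5 * dt * k1w, k2w = acc(th + 0.5 * dt * k1t, om + 0.5 * dt * k1w);
      double k3t = om + 0.5 * dt * k2w, k3w = acc(th + 0.5 * dt * k2t, om + 0.5 * dt * k2w);
      double k4t = om + dt * k3w, k4w = acc(th + dt * k3t, om + dt * k3w);
      th += dt / 6.0 * (k1t + 2*k2t + 2*k3t + k4t);
      om += dt / 6.0 * (k1w + 2*k2w + 2*k3w + k4w);
    }

    // 9. record
    if (i % decim == 0) {
      int rrow = i / decim;
      rec_t[rrow] = t; rec_th[rrow] = th; rec_om[rrow] = om;
      rec_Tm[rrow] = Tm; rec_Ta[rrow] = Ta;
      rec_xcom[rrow] = h_b * std::sin(th);
      rec_xcop[rrow] = Ta / (m_b * g_b);
      for (int k = 0; k < NM; ++k) {
        rec_Lf(rrow, k) = Lf[k]; rec_Vf(rrow, k) = Vf[k];
        rec_Ft(rrow, k) = Ft_norm[k] * mtu[k].F0;
        rec_as(rrow, k) = a_slow[k]; rec_af(rrow, k) = a_fast[k];
        rec_Ia(rrow, k) = Ia_rate[k]; rec_II(rrow, k) = II_rate[k];
        rec_Ib(rrow, k) = Ib_rate[k];
      }
    }

    if (std::fabs(th) > fall_rad) { fell_at = i; break; }
    if ((i & 1023) == 0) {
      bool ok = std::isfinite(th) && std::isfinite(om);
      for (int k = 0; k < NM; ++k) ok = ok && std::isfinite(Lf[k]) && std::isfinite(Vf[k]);
      if (have_neurons && pool.n > 0) ok = ok && std::isfinite(pool.Vs[0]);
      if (!ok) stop("numerical blow-up at t=%.4f s (non-finite state)", t);
    }
  }

  std::string status = (fell_at >= 0) ? "fell" : "completed";
  return List::create(
    _["t"] = rec_t, _["theta"] = rec_th, _["omega"] = rec_om,
    _["T_muscles"] = rec_Tm, _["T_a"] = rec_Ta,
    _["x_com"] = rec_xcom, _["x_cop"] = rec_xcop,
    _["L_f"] = rec_Lf, _["V_f"] = rec_Vf, _["F_tendon"] = rec_Ft,
    _["a_slow"] = rec_as, _["a_fast"] = rec_af,
    _["Ia"] = rec_Ia, _["II"] = rec_II, _["Ib"] = rec_Ib,
    _["emg"] = rec_emg,
    _["spike_t"] = wrap(sp_t), _["spike_id"] = wrap(sp_id),
    _["aff_t"] = wrap(af_t), _["aff_id"] = wrap(af_id),
    _["status"] = status,
    _["fell_at"] = fell_at < 0 ? R_NilValue : wrap(fell_at * dt));
}
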