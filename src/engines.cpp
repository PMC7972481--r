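// Simulation engines: a conductance-based LIF spiking backend and a
// rate-unit backend, both with two-trace eligibility plasticity applied at
// neuromodulator (reward) events.  Time is in ms, rates in Hz throughout.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

struct TraceParamsC {
  double tau_p, tau_d, eta_p, eta_d, tmax_p, tmax_d;
  double r_th, eta_lr, refractory, w_min, w_max;
};

TraceParamsC as_trace_params(const List& tp) {
  TraceParamsC p;
  p.tau_p = as<double>(tp["tau_p"]);
  p.tau_d = as<double>(tp["tau_d"]);
  p.eta_p = as<double>(tp["eta_p"]);
  p.eta_d = as<double>(tp["eta_d"]);
  p.tmax_p = as<double>(tp["tmax_p"]);
  p.tmax_d = as<double>(tp["tmax_d"]);
  p.r_th = as<double>(tp["r_th"]);
  p.eta_lr = as<double>(tp["eta_lr"]);
  p.refractory = as<double>(tp["trace_refractory"]);
  p.w_min = as<double>(tp["w_min"]);
  p.w_max = as<double>(tp["w_max"]);
  return p;
}

// Euler step of tau_a dT/dt = -T + eta_a H (Tmax_a - T), clamped to [0, Tmax].
inline void trace_step(arma::mat& T, const arma::mat& H, double dt,
                       double tau, double eta, double tmax) {
  T += (dt / tau) * (-T + eta * (H % (tmax - T)));
  T.clamp(0.0, tmax);
}

inline void trace_decay(arma::mat& T, double dt, double tau, double tmax) {
  T *= (1.0 - dt / tau);
  T.clamp(0.0, tmax);
}

}  // namespace

// ---------------------------------------------------------------------------
// Spiking engine
//
// pops: list of population descriptors (size, C, gL, EL, EE, EI, vth, vreset,
//   tref, sigma, tau_s, rho_syn, tau_r, tau_s_in).
// groups: list of synapse groups (pre, post [1-based], cls "E"/"I",
//   uniform flag + w scalar or full W [npost x npre], plastic flag, tp).
// inputs: matrix with columns (t0, t1, pop, rate_hz, weight); intervals must
//   be sorted and non-overlapping within each population.
// rewards: neuromodulator event times (consumed only when learn = TRUE).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List sim_spiking_cpp(List pops, List groups, NumericMatrix inputs,
                     NumericVector rewards, double t_total, double dt,
                     bool learn, double record_dt,
                     NumericVector snapshot_times, bool record_spikes,
                     double rate_ceiling, double trace_dt,
                     Nullable<List> init_state) {
  const int npop = pops.size();
  const int ngrp = groups.size();

  // population parameters
  std::vector<int> n(npop);
  std::vector<double> C(npop), gL(npop), EL(npop), EE(npop), EI(npop),
      vreset(npop), tref(npop), sigma(npop), tau_s(npop),
      rho(npop), tau_r(npop), tau_s_in(npop);
  std::vector<arma::vec> vth(npop);
  for (int p = 0; p < npop; ++p) {
    List pp = pops[p];
    n[p] = as<int>(pp["size"]);
    C[p] = as<double>(pp["C"]);
    gL[p] = as<double>(pp["gL"]);
    EL[p] = as<double>(pp["EL"]);
    EE[p] = as<double>(pp["EE"]);
    EI[p] = as<double>(pp["EI"]);
    {
      arma::vec vv = as<arma::vec>(pp["vth"]);
      vth[p] = (vv.n_elem == 1) ? arma::vec(n[p], arma::fill::value(vv[0]))
                                : vv;
      if ((int)vth[p].n_elem != n[p])
        stop("vth vector of population %d has wrong length", p + 1);
    }
    vreset[p] = as<double>(pp["vreset"]);
    tref[p] = as<double>(pp["tref"]);
    sigma[p] = as<double>(pp["sigma"]);
    tau_s[p] = as<double>(pp["tau_s"]);
    rho[p] = as<double>(pp["rho_syn"]);
    tau_r[p] = as<double>(pp["tau_r"]);
    tau_s_in[p] = as<double>(pp["tau_s_in"]);
  }

  // state
  std::vector<arma::vec> v(npop), s(npop), refr(npop), r(npop), s_in(npop);
  std::vector<arma::vec> gE(npop), gI(npop);
  std::vector<std::vector<char>> spiked(npop);
  for (int p = 0; p < npop; ++p) {
    v[p] = arma::vec(n[p]);
    v[p].fill(EL[p]);
    s[p] = arma::zeros<arma::vec>(n[p]);
    refr[p] = arma::zeros<arma::vec>(n[p]);
    r[p] = arma::zeros<arma::vec>(n[p]);
    s_in[p] = arma::zeros<arma::vec>(n[p]);
    gE[p] = arma::zeros<arma::vec>(n[p]);
    gI[p] = arma::zeros<arma::vec>(n[p]);
    spiked[p].assign(n[p], 0);
  }
  if (init_state.isNotNull()) {
    List st(init_state);
    if (st.containsElementNamed("v")) {
      List vl = st["v"];
      for (int p = 0; p < npop; ++p) v[p] = as<arma::vec>(vl[p]);
    }
    if (st.containsElementNamed("s")) {
      List sl = st["s"];
      for (int p = 0; p < npop; ++p) s[p] = as<arma::vec>(sl[p]);
    }
  }

  // synapse groups
  std::vector<int> g_pre(ngrp), g_post(ngrp);
  std::vector<bool> g_inh(ngrp), g_unif(ngrp), g_plastic(ngrp);
  std::vector<double> g_w(ngrp);
  std::vector<arma::mat> g_W(ngrp), g_Tp(ngrp), g_Td(ngrp);
  std::vector<TraceParamsC> g_tp(ngrp);
  std::vector<double> g_lock(ngrp, 0.0);
  std::vector<int> plastic_idx;
  for (int g = 0; g < ngrp; ++g) {
    List gg = groups[g];
    g_pre[g] = as<int>(gg["pre"]) - 1;
    g_post[g] = as<int>(gg["post"]) - 1;
    g_inh[g] = as<std::string>(gg["cls"]) == "I";
    g_unif[g] = as<bool>(gg["uniform"]);
    g_plastic[g] = as<bool>(gg["plastic"]);
    if (g_unif[g]) {
      g_w[g] = as<double>(gg["w"]);
    } else {
      g_W[g] = as<arma::mat>(gg["W"]);
      if ((int)g_W[g].n_rows != n[g_post[g]] ||
          (int)g_W[g].n_cols != n[g_pre[g]])
        stop("weight matrix of group %d has wrong shape", g + 1);
    }
    if (g_plastic[g]) {
      g_tp[g] = as_trace_params(gg["tp"]);
      g_Tp[g] = arma::zeros<arma::mat>(n[g_post[g]], n[g_pre[g]]);
      g_Td[g] = arma::zeros<arma::mat>(n[g_post[g]], n[g_pre[g]]);
      plastic_idx.push_back(g);
    }
  }
  const int nplast = plastic_idx.size();

  // inputs grouped by population
  std::vector<std::vector<int>> in_rows(npop);
  for (int i = 0; i < inputs.nrow(); ++i)
    in_rows[(int)inputs(i, 2) - 1].push_back(i);
  std::vector<size_t> in_ptr(npop, 0);

  const int nsteps = (int)std::round(t_total / dt);
  const int rec_stride = std::max(1, (int)std::round(record_dt / dt));
  const int tr_stride = std::max(1, (int)std::round(trace_dt / dt));
  const double dt_tr = dt * tr_stride;
  const double sqrtdt = std::sqrt(dt);

  std::vector<double> dec_s(npop), dec_r(npop), dec_sin(npop), rinc(npop);
  for (int p = 0; p < npop; ++p) {
    dec_s[p] = std::exp(-dt / tau_s[p]);
    dec_r[p] = std::exp(-dt / tau_r[p]);
    dec_sin[p] = std::exp(-dt / tau_s_in[p]);
    rinc[p] = 1000.0 / tau_r[p];  // Hz per spike after delta integration
  }

  // recording buffers
  const int nrec = nsteps / rec_stride + 1;
  arma::mat rec_rates(nrec, npop, arma::fill::zeros);
  arma::vec rec_time(nrec, arma::fill::zeros);
  arma::mat rec_tp(nrec, nplast, arma::fill::zeros);
  arma::mat rec_td(nrec, nplast, arma::fill::zeros);
  arma::mat rec_h(nrec, nplast, arma::fill::zeros);
  int rec_i = 0;
  std::vector<double> sp_t, sp_pop, sp_idx;
  const int nsnap = snapshot_times.size();
  arma::mat snaps(nsnap, nplast, arma::fill::zeros);
  int snap_i = 0;
  int rew_i = 0;
  const int nrew = rewards.size();
  arma::mat rew_log(learn ? nrew : 0, 1 + 3 * nplast, arma::fill::zeros);

  for (int step = 0; step <= nsteps; ++step) {
    const double t = step * dt;

    // neuromodulator events: convert traces to weights, consume, lock out
    if (learn) {
      while (rew_i < nrew && t >= rewards[rew_i] - 1e-9) {
        rew_log(rew_i, 0) = rewards[rew_i];
        for (int k = 0; k < nplast; ++k) {
          int g = plastic_idx[k];
          const TraceParamsC& q = g_tp[g];
          rew_log(rew_i, 1 + 3 * k) = arma::mean(arma::mean(g_Tp[g]));
          rew_log(rew_i, 2 + 3 * k) = arma::mean(arma::mean(g_Td[g]));
          g_W[g] += q.eta_lr * (g_Tp[g] - g_Td[g]);
          g_W[g].clamp(q.w_min, q.w_max);
          g_Tp[g].zeros();
          g_Td[g].zeros();
          g_lock[g] = q.refractory;
          rew_log(rew_i, 3 + 3 * k) = arma::mean(arma::mean(g_W[g]));
        }
        ++rew_i;
      }
    }

    // conductances
    for (int p = 0; p < npop; ++p) {
      gE[p].zeros();
      gI[p].zeros();
    }
    for (int g = 0; g < ngrp; ++g) {
      arma::vec& tgt = g_inh[g] ? gI[g_post[g]] : gE[g_post[g]];
      if (g_unif[g])
        tgt += g_w[g] * arma::accu(s[g_pre[g]]);
      else
        tgt += g_W[g] * s[g_pre[g]];
    }

    // external input: current interval per population
    for (int p = 0; p < npop; ++p) {
      double in_rate = 0.0, in_w = 0.0;
      const std::vector<int>& rows = in_rows[p];
      while (in_ptr[p] < rows.size() && t >= inputs(rows[in_ptr[p]], 1))
        ++in_ptr[p];
      if (in_ptr[p] < rows.size()) {
        int rr = rows[in_ptr[p]];
        if (t >= inputs(rr, 0)) {
          in_rate = inputs(rr, 3);
          in_w = inputs(rr, 4);
        }
      }
      const double p_spk = in_rate * dt * 1e-3;

      arma::vec& vp = v[p];
      arma::vec& sp = s[p];
      arma::vec& rp = r[p];
      arma::vec& sip = s_in[p];
      arma::vec& rfp = refr[p];
      for (int i = 0; i < n[p]; ++i) {
        bool spk = false;
        if (rfp[i] > 0.0) {
          rfp[i] -= dt;
          vp[i] = vreset[p];
        } else {
          const double ge = gE[p][i] + in_w * sip[i];
          double dv = (dt / C[p]) * (gL[p] * (EL[p] - vp[i]) +
                                     ge * (EE[p] - vp[i]) +
                                     gI[p][i] * (EI[p] - vp[i]));
          if (sigma[p] > 0.0) dv += sigma[p] * sqrtdt * norm_rand();
          vp[i] += dv;
          if (!std::isfinite(vp[i]))
            stop("non-finite membrane potential: population %d neuron %d at step %d",
                 p + 1, i + 1, step);
          if (vp[i] >= vth[p][i]) {
            spk = true;
            vp[i] = vreset[p];
            rfp[i] = tref[p];
          }
        }
        // synaptic decay precedes the spike increment within a step
        sp[i] *= dec_s[p];
        rp[i] *= dec_r[p];
        sip[i] *= dec_sin[p];
        if (spk) {
          sp[i] += rho[p] * (1.0 - sp[i]);
          rp[i] += rinc[p];
          if (record_spikes) {
            sp_t.push_back(t);
            sp_pop.push_back(p + 1);
            sp_idx.push_back(i + 1);
          }
        }
        if (p_spk > 0.0 && unif_rand() < p_spk)
          sip[i] += rho[p] * (1.0 - sip[i]);
      }
    }

    // eligibility traces (sub-sampled; rate estimates vary on tau_r >> dt)
    if (learn && step % tr_stride == 0) {
      for (int k = 0; k < nplast; ++k) {
        int g = plastic_idx[k];
        const TraceParamsC& q = g_tp[g];
        bool active = false;
        if (g_lock[g] > 0.0) {
          g_lock[g] -= dt_tr;
        } else {
          arma::vec rpre = r[g_pre[g]];
          arma::vec rpost = r[g_post[g]];
          rpre.elem(arma::find(rpre <= q.r_th)).zeros();
          rpost.elem(arma::find(rpost <= q.r_th)).zeros();
          if (rpre.max() > 0.0 && rpost.max() > 0.0) {
            arma::mat H = rpost * rpre.t();
            trace_step(g_Tp[g], H, dt_tr, q.tau_p, q.eta_p, q.tmax_p);
            trace_step(g_Td[g], H, dt_tr, q.tau_d, q.eta_d, q.tmax_d);
            active = true;
          }
        }
        if (!active) {
          trace_decay(g_Tp[g], dt_tr, q.tau_p, q.tmax_p);
          trace_decay(g_Td[g], dt_tr, q.tau_d, q.tmax_d);
        }
      }
    }

    // recording
    if (step % rec_stride == 0 && rec_i < nrec) {
      rec_time(rec_i) = t;
      for (int p = 0; p < npop; ++p) rec_rates(rec_i, p) = arma::mean(r[p]);
      for (int k = 0; k < nplast; ++k) {
        int g = plastic_idx[k];
        rec_tp(rec_i, k) = arma::mean(arma::mean(g_Tp[g]));
        rec_td(rec_i, k) = arma::mean(arma::mean(g_Td[g]));
        const TraceParamsC& q = g_tp[g];
        arma::vec rpre = r[g_pre[g]];
        arma::vec rpost = r[g_post[g]];
        rpre.elem(arma::find(rpre <= q.r_th)).zeros();
        rpost.elem(arma::find(rpost <= q.r_th)).zeros();
        rec_h(rec_i, k) = arma::mean(rpost) * arma::mean(rpre);
      }
      ++rec_i;
      for (int p = 0; p < npop; ++p)
        if (arma::mean(r[p]) > rate_ceiling)
          stop("divergent rates: population %d exceeded %g Hz at t = %g ms",
               p + 1, rate_ceiling, t);
    }

    while (snap_i < nsnap && t >= snapshot_times[snap_i] - 1e-9) {
      for (int k = 0; k < nplast; ++k)
        snaps(snap_i, k) = arma::mean(arma::mean(g_W[plastic_idx[k]]));
      ++snap_i;
    }
  }

  List w_final(ngrp);
  for (int g = 0; g < ngrp; ++g)
    w_final[g] = g_unif[g] ? wrap(g_w[g]) : wrap(g_W[g]);

  arma::mat spikes(sp_t.size(), 3);
  for (size_t i = 0; i < sp_t.size(); ++i) {
    spikes(i, 0) = sp_t[i];
    spikes(i, 1) = sp_pop[i];
    spikes(i, 2) = sp_idx[i];
  }

  return List::create(
      _["time"] = rec_time.head(rec_i), _["rates"] = rec_rates.head_rows(rec_i),
      _["trace_p"] = rec_tp.head_rows(rec_i),
      _["trace_d"] = rec_td.head_rows(rec_i),
      _["hebb"] = rec_h.head_rows(rec_i), _["spikes"] = spikes,
      _["weights"] = w_final, _["snapshots"] = snaps,
      _["reward_log"] = rew_log);
}

// ---------------------------------------------------------------------------
// Rate engine
//
// One unit per population.  W is a dense signed weight matrix (n x n).
// Plastic entries are single weights W(post, pre) with scalar traces.
// An optional three-stage extension adds a fixed recurrent reservoir and a
// binary sparse pattern net feeding back onto Timer units through Hebbian
// weights Q.
// ---------------------------------------------------------------------------

namespace {
inline double xi_transfer(double u, double th, double uc, double vs) {
  if (u <= th) return 0.0;
  const double x = (u - th) / (uc - th);
  if (u < uc) return vs * x * x;
  return 2.0 * vs * std::sqrt(x - 0.75);
}
}  // namespace

// [[Rcpp::export]]
List sim_rate_cpp(arma::mat W, arma::vec tau_u, double theta, double u_c,
                  double v_scale, NumericMatrix inputs,
                  IntegerMatrix plastic, List trace_params,
                  NumericVector rewards, double t_total, double dt, bool learn,
                  double record_dt, NumericVector snapshot_times,
                  double rate_ceiling, Nullable<NumericVector> init_u,
                  Nullable<List> three_stage) {
  const int nu = W.n_rows;
  arma::vec u(nu, arma::fill::zeros);
  if (init_u.isNotNull()) u = as<arma::vec>(NumericVector(init_u));

  // plastic entries: columns (pre, post, class) 1-based; class indexes
  // trace_params
  const int npl = plastic.nrow();
  std::vector<TraceParamsC> cls;
  for (int i = 0; i < trace_params.size(); ++i)
    cls.push_back(as_trace_params(trace_params[i]));
  arma::vec Tp(npl, arma::fill::zeros), Td(npl, arma::fill::zeros);
  arma::vec lock(npl, arma::fill::zeros);

  // three-stage extension
  bool ts = three_stage.isNotNull();
  arma::mat J, Wres, O, Q;
  arma::uvec mess_idx, timer_idx;
  arma::vec u_res, nu_pat;
  double tau_net = 1, theta_m = 0, theta_o = 0, q_max = 0, q_rth = 0;
  bool q_learn = false, record_nu = false, q_drive = true;
  if (ts) {
    List t3(three_stage);
    J = as<arma::mat>(t3["J"]);
    Wres = as<arma::mat>(t3["W_res"]);
    O = as<arma::mat>(t3["O"]);
    Q = as<arma::mat>(t3["Q"]);
    mess_idx = as<arma::uvec>(t3["mess_idx"]) - 1;
    timer_idx = as<arma::uvec>(t3["timer_idx"]) - 1;
    tau_net = as<double>(t3["tau_net"]);
    theta_m = as<double>(t3["theta_m"]);
    theta_o = as<double>(t3["theta_o"]);
    q_max = as<double>(t3["q_max"]);
    if (t3.containsElementNamed("q_rth")) q_rth = as<double>(t3["q_rth"]);
    q_learn = as<bool>(t3["q_learn"]);
    if (t3.containsElementNamed("q_drive")) q_drive = as<bool>(t3["q_drive"]);
    record_nu = as<bool>(t3["record_nu"]);
    u_res = arma::zeros<arma::vec>(Wres.n_rows);
    if (t3.containsElementNamed("u_res0") && !Rf_isNull(t3["u_res0"]))
      u_res = as<arma::vec>(t3["u_res0"]);
    nu_pat = arma::zeros<arma::vec>(O.n_rows);
  }

  std::vector<std::vector<int>> in_rows(nu);
  for (int i = 0; i < inputs.nrow(); ++i)
    in_rows[(int)inputs(i, 2) - 1].push_back(i);
  std::vector<size_t> in_ptr(nu, 0);

  const int nsteps = (int)std::round(t_total / dt);
  const int rec_stride = std::max(1, (int)std::round(record_dt / dt));
  const int nrec = nsteps / rec_stride + 1;
  arma::mat rec_r(nrec, nu, arma::fill::zeros);
  arma::vec rec_time(nrec, arma::fill::zeros);
  arma::mat rec_tp(nrec, npl), rec_td(nrec, npl), rec_h(nrec, npl);
  rec_tp.zeros();
  rec_td.zeros();
  rec_h.zeros();
  arma::umat rec_nu_mat;
  if (ts && record_nu) rec_nu_mat.zeros(O.n_rows, nrec);
  int rec_i = 0;
  const int nsnap = snapshot_times.size();
  arma::mat snaps(nsnap, npl, arma::fill::zeros);
  int snap_i = 0;
  int rew_i = 0;
  const int nrew = rewards.size();
  arma::mat rew_log(learn ? nrew : 0, 1 + 4 * npl, arma::fill::zeros);

  arma::vec rr(nu, arma::fill::zeros), I_ext(nu);

  for (int step = 0; step <= nsteps; ++step) {
    const double t = step * dt;
    for (int i = 0; i < nu; ++i) rr[i] = xi_transfer(u[i], theta, u_c, v_scale);

    // reward events
    if (learn) {
      while (rew_i < nrew && t >= rewards[rew_i] - 1e-9) {
        rew_log(rew_i, 0) = rewards[rew_i];
        for (int k = 0; k < npl; ++k) {
          const TraceParamsC& q = cls[plastic(k, 2) - 1];
          const int pre = plastic(k, 0) - 1, post = plastic(k, 1) - 1;
          rew_log(rew_i, 1 + 4 * k) = Tp[k];
          rew_log(rew_i, 2 + 4 * k) = Td[k];
          const double hp = (rr[pre] > q.r_th && rr[post] > q.r_th)
                                ? rr[pre] * rr[post]
                                : 0.0;
          rew_log(rew_i, 3 + 4 * k) = hp;
          double w = W(post, pre) + q.eta_lr * (Tp[k] - Td[k]);
          W(post, pre) = std::min(q.w_max, std::max(q.w_min, w));
          Tp[k] = 0.0;
          Td[k] = 0.0;
          lock[k] = q.refractory;
          rew_log(rew_i, 4 + 4 * k) = W(post, pre);
        }
        ++rew_i;
      }
    }

    // external input
    I_ext.zeros();
    for (int p = 0; p < nu; ++p) {
      const std::vector<int>& rows = in_rows[p];
      while (in_ptr[p] < rows.size() && t >= inputs(rows[in_ptr[p]], 1))
        ++in_ptr[p];
      if (in_ptr[p] < rows.size()) {
        int rrow = rows[in_ptr[p]];
        if (t >= inputs(rrow, 0)) I_ext[p] += inputs(rrow, 3);
      }
    }

    // sparse-pattern feedback onto Timer units
    if (ts) {
      arma::vec rm = rr.elem(mess_idx);
      const bool gate = arma::any(rm > theta_m);
      arma::vec drive = O * arma::tanh(u_res);
      nu_pat.zeros();
      if (gate)
        nu_pat.elem(arma::find(drive > theta_o)).ones();
      if (q_drive) {
        arma::vec fb = Q * nu_pat;
        for (size_t j = 0; j < timer_idx.n_elem; ++j)
          I_ext[timer_idx[j]] += fb[j];
      }
      if (q_learn && arma::any(nu_pat > 0)) {
        // dQ/dt = r_j nu_m, bounded in [0, Qmax]; rates in Hz, dt in ms.
        // Timer rates are gated at q_rth so the decaying tail of the element
        // that is ending does not wire itself to its own transition pattern.
        arma::vec rt = rr.elem(timer_idx);
        rt.elem(arma::find(rt <= q_rth)).zeros();
        Q += (dt * 1e-3) * (rt * nu_pat.t());
        Q.clamp(0.0, q_max);
      }
      // reservoir dynamics
      arma::vec psi = rm - theta_m;
      psi.elem(arma::find(psi < 0.0)).zeros();
      u_res += (dt / tau_net) * (-u_res + J * psi + Wres * arma::tanh(u_res));
      if (!u_res.is_finite()) stop("non-finite reservoir state at t = %g", t);
    }

    // unit dynamics: tau du/dt = -u + sum_a W^a xi(u) + I_ext
    arma::vec net = W * rr + I_ext;
    u += (dt / tau_u) % (-u + net);
    for (int i = 0; i < nu; ++i)
      if (!std::isfinite(u[i]))
        stop("non-finite activation: unit %d at step %d", i + 1, step);

    // traces
    if (learn) {
      for (int k = 0; k < npl; ++k) {
        const TraceParamsC& q = cls[plastic(k, 2) - 1];
        double H = 0.0;
        if (lock[k] > 0.0) {
          lock[k] -= dt;
        } else {
          const int pre = plastic(k, 0) - 1, post = plastic(k, 1) - 1;
          if (rr[pre] > q.r_th && rr[post] > q.r_th) H = rr[pre] * rr[post];
        }
        Tp[k] += (dt / q.tau_p) * (-Tp[k] + q.eta_p * H * (q.tmax_p - Tp[k]));
        Td[k] += (dt / q.tau_d) * (-Td[k] + q.eta_d * H * (q.tmax_d - Td[k]));
        Tp[k] = std::min(q.tmax_p, std::max(0.0, Tp[k]));
        Td[k] = std::min(q.tmax_d, std::max(0.0, Td[k]));
      }
    }

    if (step % rec_stride == 0 && rec_i < nrec) {
      rec_time[rec_i] = t;
      for (int i = 0; i < nu; ++i) {
        rec_r(rec_i, i) = xi_transfer(u[i], theta, u_c, v_scale);
        if (rec_r(rec_i, i) > rate_ceiling)
          stop("divergent rate: unit %d exceeded %g Hz at t = %g ms", i + 1,
               rate_ceiling, t);
      }
      for (int k = 0; k < npl; ++k) {
        rec_tp(rec_i, k) = Tp[k];
        rec_td(rec_i, k) = Td[k];
        const TraceParamsC& q = cls[plastic(k, 2) - 1];
        const int pre = plastic(k, 0) - 1, post = plastic(k, 1) - 1;
        rec_h(rec_i, k) = (rr[pre] > q.r_th && rr[post] > q.r_th)
                              ? rr[pre] * rr[post]
                              : 0.0;
      }
      if (ts && record_nu) rec_nu_mat.col(rec_i) = arma::conv_to<arma::uvec>::from(nu_pat);
      ++rec_i;
    }
    while (snap_i < nsnap && t >= snapshot_times[snap_i] - 1e-9) {
      for (int k = 0; k < npl; ++k)
        snaps(snap_i, k) = W(plastic(k, 1) - 1, plastic(k, 0) - 1);
      ++snap_i;
    }
  }

  List out = List::create(
      _["time"] = rec_time.head(rec_i), _["rates"] = rec_r.head_rows(rec_i),
      _["trace_p"] = rec_tp.head_rows(rec_i),
      _["trace_d"] = rec_td.head_rows(rec_i), _["hebb"] = rec_h.head_rows(rec_i),
      _["W"] = W, _["snapshots"] = snaps, _["reward_log"] = rew_log,
      _["u_final"] = u);
  if (ts) {
    out["Q"] = Q;
    out["u_res_final"] = u_res;
    if (record_nu) out["nu"] = rec_nu_mat.cols(0, rec_i - 1);
  }
  return out;
}
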