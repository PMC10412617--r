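// Time-stepped integration of the clustered AdEx/LIF networks.
//
// Conventions (mirrored exactly by the plain-R reference stepper used in the
// test suite):
//  * forward Euler, all derivatives evaluated at the start-of-step state;
//  * spikes are detected after the Euler update and stamped at t + dt;
//  * a spike emitted at step n enters the postsynaptic kernel traces at step
//    n + 1 (traces decay first, then receive the pending impulses);
//  * external Poisson counts generated at step n enter the traces at step n;
//  * during the absolute refractory period the membrane stays clamped at V_r
//    while the adaptive threshold, adaptation current and synaptic traces
//    keep evolving;
//  * the AdEx exponential argument is capped and the membrane clamped just
//    above the detection cutoff to keep the blow-up finite between checks.

#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

struct Pop {
  int nE = 0, nI = 0, n = 0, nclust = 0;
  const double* W = nullptr;   // n x n, column = presynaptic neuron
  std::vector<int> cluster;    // per E neuron, 0-based
  double beta = 0;
  double w_ext_E = 0, w_ext_I = 0;
  std::vector<double> base_rate, rate;  // kHz, per neuron
  // cached Poisson inversion tables, one per distinct rate
  std::vector<int> rate_idx;
  std::vector<double> rate_vals;
  std::vector<std::vector<double>> rate_cum;
  // state
  std::vector<double> V, a, vt, ref_until, last_spike;
  std::vector<double> eEd, eEr, eId, eIr;  // kernel traces (decay / rise)
  std::vector<double> pendE, pendI;        // impulses accumulated for next step
  std::vector<int> spiked;                 // this step's spikers
  // external count override (testing): n x n_steps, column-major
  const double* ext = nullptr;
};

inline double getd(const List& l, const char* nm) { return as<double>(l[nm]); }

// Cumulative Poisson probabilities for inversion sampling (the per-step means
// are small, so a linear scan over the table is fast and exact to 1e-15).
std::vector<double> pois_cum_table(double lam) {
  std::vector<double> cum;
  double p = std::exp(-lam), c = p;
  cum.push_back(c);
  int k = 0;
  while (c < 1.0 - 1e-15 && k < 200) {
    ++k;
    p *= lam / k;
    c += p;
    cum.push_back(c);
  }
  return cum;
}

inline int pois_draw(const std::vector<double>& cum, double u) {
  int k = 0;
  const int kmax = (int)cum.size() - 1;
  while (k < kmax && u > cum[k]) ++k;
  return k;
}

void rebuild_rate_cache(Pop& pp, double dt) {
  pp.rate_vals.clear();
  pp.rate_cum.clear();
  pp.rate_idx.assign(pp.n, -1);
  for (int i = 0; i < pp.n; ++i) {
    double lam = pp.rate[i] * dt;
    if (lam <= 0) { pp.rate_idx[i] = -1; continue; }
    int idx = -1;
    for (size_t k = 0; k < pp.rate_vals.size(); ++k)
      if (pp.rate_vals[k] == lam) { idx = (int)k; break; }
    if (idx < 0) {
      pp.rate_vals.push_back(lam);
      pp.rate_cum.push_back(pois_cum_table(lam));
      idx = (int)pp.rate_vals.size() - 1;
    }
    pp.rate_idx[i] = idx;
  }
}

}  // namespace

// [[Rcpp::export(name = ".sim_run_cpp")]]
List sim_run_cpp(List pops_in, List npar, List syn,
                 SEXP plastic_W_sexp, List plast,
                 int plastic_pre, int plastic_post,
                 SEXP stp_w_sexp, List stp,
                 int stp_pre, int stp_post,
                 NumericMatrix stim_events,
                 double t0, double duration, double dt,
                 NumericVector snapshot_times,
                 int seed, bool record_spikes,
                 List init_state, List ext_override,
                 int plast_every = 1) {
  if (plast_every < 1) plast_every = 1;
  const int P = pops_in.size();
  std::vector<Pop> pops(P);

  // neuron parameters
  const double tau_E = getd(npar, "tau_E"), tau_I = getd(npar, "tau_I");
  const double tau_abs = getd(npar, "tau_abs");
  const double E_rev_E = getd(npar, "E_rev_E"), E_rev_I = getd(npar, "E_rev_I");
  const double E_L_E = getd(npar, "E_L_E"), E_L_I = getd(npar, "E_L_I");
  const double V_r = getd(npar, "V_r"), C_mem = getd(npar, "C_mem");
  const double Delta_T = getd(npar, "Delta_T"), tau_T = getd(npar, "tau_T");
  const double V_T = getd(npar, "V_T"), A_T = getd(npar, "A_T");
  const double tau_a = getd(npar, "tau_a"), alpha = getd(npar, "alpha");
  const double cutoff = getd(npar, "spike_cutoff");
  const double exp_arg_cap = 50.0;
  const double V_clamp_hi = cutoff + 10.0;

  // synaptic kernels
  const double tdE = getd(syn, "tau_d_E"), trE = getd(syn, "tau_r_E");
  const double tdI = getd(syn, "tau_d_I"), trI = getd(syn, "tau_r_I");
  if (tdE == trE || tdI == trI)
    stop("invalid kernel: decay and rise time constants must differ");
  const double decEd = std::exp(-dt / tdE), decEr = std::exp(-dt / trE);
  const double decId = std::exp(-dt / tdI), decIr = std::exp(-dt / trI);
  const double normE = 1.0 / (tdE - trE), normI = 1.0 / (tdI - trI);

  std::mt19937 rng(static_cast<uint32_t>(seed));
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  const bool have_state = init_state.size() > 0;

  // ---- set up populations -------------------------------------------------
  std::vector<NumericMatrix> Wmats(P);  // keep alive
  for (int p = 0; p < P; ++p) {
    List pl = pops_in[p];
    Pop& pp = pops[p];
    pp.nE = as<int>(pl["n_E"]);
    pp.nI = as<int>(pl["n_I"]);
    pp.n = pp.nE + pp.nI;
    pp.nclust = as<int>(pl["n_clusters"]);
    Wmats[p] = as<NumericMatrix>(pl["W"]);
    if (Wmats[p].nrow() != pp.n || Wmats[p].ncol() != pp.n)
      stop("population %d: weight matrix dimension mismatch", p + 1);
    pp.W = REAL(Wmats[p]);
    IntegerVector cl = pl["cluster_id"];
    pp.cluster.assign(cl.begin(), cl.end());
    for (int& c : pp.cluster) --c;
    pp.beta = as<double>(pl["beta"]);
    List drv = pl["drive"];
    pp.w_ext_E = getd(drv, "W_ext_E");
    pp.w_ext_I = getd(drv, "W_ext_I");
    pp.base_rate.assign(pp.n, 0.0);
    for (int i = 0; i < pp.n; ++i)
      pp.base_rate[i] = (i < pp.nE) ? getd(drv, "r_ext_E") : getd(drv, "r_ext_I");
    pp.rate = pp.base_rate;

    pp.V.assign(pp.n, V_r);
    pp.a.assign(pp.nE, 0.0);
    pp.vt.assign(pp.nE, V_T);
    pp.ref_until.assign(pp.n, -1e18);
    pp.last_spike.assign(pp.n, -1e18);
    pp.eEd.assign(pp.n, 0.0); pp.eEr.assign(pp.n, 0.0);
    pp.eId.assign(pp.n, 0.0); pp.eIr.assign(pp.n, 0.0);
    pp.pendE.assign(pp.n, 0.0); pp.pendI.assign(pp.n, 0.0);

    if (have_state) {
      List st = init_state[p];
      NumericVector v;
      v = st["V"];          std::copy(v.begin(), v.end(), pp.V.begin());
      v = st["a"];          std::copy(v.begin(), v.end(), pp.a.begin());
      v = st["vt"];         std::copy(v.begin(), v.end(), pp.vt.begin());
      v = st["ref_until"];  std::copy(v.begin(), v.end(), pp.ref_until.begin());
      v = st["last_spike"]; std::copy(v.begin(), v.end(), pp.last_spike.begin());
      v = st["eEd"]; std::copy(v.begin(), v.end(), pp.eEd.begin());
      v = st["eEr"]; std::copy(v.begin(), v.end(), pp.eEr.begin());
      v = st["eId"]; std::copy(v.begin(), v.end(), pp.eId.begin());
      v = st["eIr"]; std::copy(v.begin(), v.end(), pp.eIr.begin());
      v = st["pendE"]; std::copy(v.begin(), v.end(), pp.pendE.begin());
      v = st["pendI"]; std::copy(v.begin(), v.end(), pp.pendI.begin());
    } else {
      // startup desynchronization: V ~ U(V_r, V_T)
      for (int i = 0; i < pp.n; ++i)
        pp.V[i] = V_r + (V_T - V_r) * unif(rng);
    }
    if (ext_override.size() > p && !Rf_isNull(ext_override[p])) {
      NumericMatrix m = ext_override[p];
      pp.ext = REAL(m);
    }
    rebuild_rate_cache(pp, dt);
  }

  // ---- plastic inter-network connection ----------------------------------
  NumericMatrix Pmat;
  double* Pw = nullptr;
  int n_pre = 0, n_post = 0;
  bool has_plastic = !Rf_isNull(plastic_W_sexp);
  std::vector<double> colsum;
  const bool plast_on = has_plastic && as<bool>(plast["enabled"]);
  double A_p = 0, Knorm = 0, tau_n = 1, w_min = 0, w_max = 0, ywin = 0;
  if (has_plastic) {
    Pmat = clone(as<NumericMatrix>(plastic_W_sexp));
    Pw = REAL(Pmat);
    n_post = Pmat.nrow();
    n_pre = Pmat.ncol();
    if (plastic_pre < 1 || plastic_post < 1)
      stop("plastic connection endpoints not set");
    if (n_pre != pops[plastic_pre - 1].nE || n_post != pops[plastic_post - 1].nE)
      stop("plastic matrix dimensions do not match the populations");
    A_p = getd(plast, "A_p"); Knorm = getd(plast, "K_norm");
    tau_n = getd(plast, "tau_n");
    w_min = getd(plast, "W_min"); w_max = getd(plast, "W_max");
    ywin = getd(plast, "coincidence_window");
    colsum.assign(n_pre, 0.0);
    for (int j = 0; j < n_pre; ++j) {
      double s = 0;
      const double* col = Pw + (size_t)j * n_post;
      for (int i = 0; i < n_post; ++i) s += col[i];
      colsum[j] = s;
    }
  }

  // ---- STP read-out connection --------------------------------------------
  bool has_stp = !Rf_isNull(stp_w_sexp);
  std::vector<double> wstp;
  bool stp_on = false, stp_depress = true;
  double stp_base = 0, stp_frac = 0, stp_tau = 1, stp_cap = 0;
  double sh_d = 0, sh_r = 0, pend_sh = 0;  // shared kernel trace (E class)
  if (has_stp) {
    NumericVector w0(stp_w_sexp);
    wstp.assign(w0.begin(), w0.end());
    stp_on = as<bool>(stp["enabled"]);
    stp_depress = as<std::string>(stp["mode"]) == "depression";
    stp_base = getd(stp, "baseline"); stp_frac = getd(stp, "step_fraction");
    stp_tau = getd(stp, "recovery_tau"); stp_cap = getd(stp, "w_cap");
    if ((int)wstp.size() != pops[stp_pre - 1].nE)
      stop("STP weight vector length does not match the presynaptic population");
  }
  if (have_state) {
    if (init_state.hasAttribute("shared")) {
      NumericVector sh = init_state.attr("shared");
      sh_d = sh[0]; sh_r = sh[1]; pend_sh = sh[2];
    }
  }

  // ---- bookkeeping ---------------------------------------------------------
  const int n_steps = (int)std::llround(duration / dt);
  std::vector<int> sp_pop, sp_neuron;
  std::vector<double> sp_time;
  if (record_spikes) {
    sp_pop.reserve(1 << 16); sp_neuron.reserve(1 << 16); sp_time.reserve(1 << 16);
  }
  int ev_idx = 0;
  const int n_ev = stim_events.nrow();
  int snap_idx = 0;
  const int n_snap = snapshot_times.size();
  List snapshots(n_snap);

  std::vector<char> y_pre, y_post;
  if (has_plastic) { y_pre.assign(n_pre, 0); y_post.assign(n_post, 0); }

  // ---- main loop -----------------------------------------------------------
  for (int step = 0; step < n_steps; ++step) {
    const double tt = t0 + step * dt;
    const double t_new = tt + dt;

    // stimulus schedule: events taking effect at or before the step start
    while (ev_idx < n_ev && stim_events(ev_idx, 0) <= tt + 1e-9) {
      int p = (int)stim_events(ev_idx, 1) - 1;
      int cl = (int)stim_events(ev_idx, 2) - 1;
      double rate = stim_events(ev_idx, 3);
      Pop& pp = pops[p];
      for (int i = 0; i < pp.nE; ++i)
        if (pp.cluster[i] == cl)
          pp.rate[i] = (rate < 0) ? pp.base_rate[i] : rate;
      rebuild_rate_cache(pp, dt);
      ++ev_idx;
    }

    // 1) synaptic traces: decay, then pending recurrent + fresh external input
    for (int p = 0; p < P; ++p) {
      Pop& pp = pops[p];
      for (int i = 0; i < pp.n; ++i) {
        double ext_cnt;
        if (pp.ext) {
          ext_cnt = pp.ext[(size_t)step * pp.n + i];
        } else {
          const int ri = pp.rate_idx[i];
          ext_cnt = (ri >= 0) ? pois_draw(pp.rate_cum[ri], unif(rng)) : 0.0;
        }
        double ext_imp = ext_cnt * ((i < pp.nE) ? pp.w_ext_E : pp.w_ext_I);
        double impE = pp.pendE[i] + ext_imp;  // external drive is excitatory
        pp.eEd[i] = pp.eEd[i] * decEd + impE;
        pp.eEr[i] = pp.eEr[i] * decEr + impE;
        pp.eId[i] = pp.eId[i] * decId + pp.pendI[i];
        pp.eIr[i] = pp.eIr[i] * decIr + pp.pendI[i];
        pp.pendE[i] = 0.0;
        pp.pendI[i] = 0.0;
      }
    }
    // shared read-out trace
    if (has_stp) {
      sh_d = sh_d * decEd + pend_sh;
      sh_r = sh_r * decEr + pend_sh;
      pend_sh = 0.0;
    }
    const double g_shared = has_stp ? (sh_d - sh_r) * normE : 0.0;

    // 2) membrane updates and spike detection
    for (int p = 0; p < P; ++p) {
      Pop& pp = pops[p];
      pp.spiked.clear();
      const bool is_stp_post = has_stp && (p == stp_post - 1);
      for (int i = 0; i < pp.n; ++i) {
        double gE = (pp.eEd[i] - pp.eEr[i]) * normE;
        double gI = (pp.eId[i] - pp.eIr[i]) * normI;
        const bool refractory = tt < pp.ref_until[i] - 1e-9;
        if (i < pp.nE) {
          if (is_stp_post) gE += g_shared;
          const double Vold = pp.V[i];
          if (!refractory) {
            double arg = (Vold - pp.vt[i]) / Delta_T;
            if (arg > exp_arg_cap) arg = exp_arg_cap;
            double dV = (E_L_E - Vold + Delta_T * std::exp(arg)) / tau_E
                        + gE * (E_rev_E - Vold) / C_mem
                        + gI * (E_rev_I - Vold) / C_mem
                        - pp.a[i] / C_mem;
            double Vn = Vold + dt * dV;
            if (Vn > V_clamp_hi) Vn = V_clamp_hi;
            pp.V[i] = Vn;
          }
          // threshold and adaptation evolve also during refractoriness
          pp.vt[i] += dt * (V_T - pp.vt[i]) / tau_T;
          pp.a[i] += dt * (-pp.a[i] + alpha * (Vold - E_L_E)) / tau_a;
          if (!std::isfinite(pp.V[i]))
            stop("numerical blow-up: population %d, E neuron %d, t = %f",
                 p + 1, i + 1, t_new);
          if (!refractory && pp.V[i] > cutoff) {
            pp.V[i] = V_r;
            pp.vt[i] = V_T + A_T;
            pp.a[i] += pp.beta;
            pp.ref_until[i] = t_new + tau_abs;
            pp.last_spike[i] = t_new;
            pp.spiked.push_back(i);
          }
        } else {
          if (!refractory) {
            double dV = (E_L_I - pp.V[i]) / tau_I
                        + gE * (E_rev_E - pp.V[i]) / C_mem
                        + gI * (E_rev_I - pp.V[i]) / C_mem;
            pp.V[i] += dt * dV;
          }
          if (!std::isfinite(pp.V[i]))
            stop("numerical blow-up: population %d, I neuron %d, t = %f",
                 p + 1, i - pp.nE + 1, t_new);
          if (!refractory && pp.V[i] > V_T) {
            pp.V[i] = V_r;
            pp.ref_until[i] = t_new + tau_abs;
            pp.last_spike[i] = t_new;
            pp.spiked.push_back(i);
          }
        }
      }
      if (record_spikes) {
        for (int i : pp.spiked) {
          sp_pop.push_back(p + 1);
          sp_neuron.push_back(i + 1);
          sp_time.push_back(t_new);
        }
      }
    }

    // 3) propagate this step's spikes into next step's pending impulses
    for (int p = 0; p < P; ++p) {
      Pop& pp = pops[p];
      for (int j : pp.spiked) {
        const double* col = pp.W + (size_t)j * pp.n;
        std::vector<double>& pend = (j < pp.nE) ? pp.pendE : pp.pendI;
        for (int i = 0; i < pp.n; ++i) pend[i] += col[i];
        if (has_plastic && p == plastic_pre - 1 && j < n_pre) {
          Pop& post = pops[plastic_post - 1];
          const double* pcol = Pw + (size_t)j * n_post;
          for (int i = 0; i < n_post; ++i) post.pendE[i] += pcol[i];
        }
      }
    }

    // 4) short-term plasticity on the read-out weights
    if (has_stp) {
      Pop& pre = pops[stp_pre - 1];
      if (stp_on) {
        const double rec = dt / stp_tau;
        for (double& w : wstp) w += rec * (stp_base - w);
        for (int j : pre.spiked) {
          if (j >= (int)wstp.size()) continue;
          pend_sh += wstp[j];
          if (stp_depress) {
            wstp[j] *= (1.0 - stp_frac);
            if (wstp[j] < 0) wstp[j] = 0;
          } else {
            wstp[j] *= (1.0 + stp_frac);
            if (wstp[j] > stp_cap) wstp[j] = stp_cap;
          }
        }
      } else {
        for (int j : pre.spiked)
          if (j < (int)wstp.size()) pend_sh += wstp[j];
      }
    }

    // 5) Hebbian + soft-normalization update of the plastic weights.
    //    The rule's time constants (tau_n = 100 ms, 15 ms eligibility) are
    //    slow relative to dt, so the update may be subsampled every
    //    `plast_every` steps with an effective step of plast_every * dt.
    //    Columns without presynaptic eligibility only relax toward K and are
    //    updated on a 10x coarser grid (exact per-step mode when
    //    plast_every = 1).
    const int slow_every = (plast_every == 1) ? 1 : 10 * plast_every;
    if (plast_on && ((step + 1) % plast_every == 0)) {
      const bool do_slow = ((step + 1) % slow_every == 0);
      const double dtp = dt * plast_every;
      const double dts = dt * slow_every;
      Pop& pre = pops[plastic_pre - 1];
      Pop& post = pops[plastic_post - 1];
      for (int j = 0; j < n_pre; ++j)
        y_pre[j] = (t_new - pre.last_spike[j]) <= ywin + 1e-9;
      for (int i = 0; i < n_post; ++i)
        y_post[i] = (t_new - post.last_spike[i]) <= ywin + 1e-9;
      const double inv_tn = 1.0 / tau_n;
      // cap the normalization move so a column sum never crosses K within one
      // (possibly coarse) update
      auto capped_share = [&](const double* col, double dev,
                              double dt_eff) -> double {
        double share = dt_eff * dev * inv_tn;
        int n_eff = 0;
        if (dev >= 0) {
          for (int i = 0; i < n_post; ++i) n_eff += (col[i] < w_max - 1e-12);
        } else {
          for (int i = 0; i < n_post; ++i) n_eff += (col[i] > w_min + 1e-12);
        }
        if (n_eff < 1) n_eff = 1;
        const double lim = std::fabs(dev) / n_eff;
        if (share > lim) share = lim;
        else if (share < -lim) share = -lim;
        return share;
      };
      for (int j = 0; j < n_pre; ++j) {
        const double dev = Knorm - colsum[j];
        double* col = Pw + (size_t)j * n_post;
        double s = 0;
        if (y_pre[j]) {
          const double share = capped_share(col, dev, dtp);
          const double pot = dtp * A_p;
          for (int i = 0; i < n_post; ++i) {
            double w = col[i] + share + (y_post[i] ? pot : 0.0);
            if (w < w_min) w = w_min; else if (w > w_max) w = w_max;
            col[i] = w; s += w;
          }
        } else if (do_slow && std::fabs(dev) > 1e-6) {
          const double share = capped_share(col, dev, dts);
          for (int i = 0; i < n_post; ++i) {
            double w = col[i] + share;
            if (w < w_min) w = w_min; else if (w > w_max) w = w_max;
            col[i] = w; s += w;
          }
        } else {
          continue;
        }
        colsum[j] = s;
      }
    }

    // 6) weight snapshots (cluster-block sums of the plastic matrix)
    while (snap_idx < n_snap && t_new >= snapshot_times[snap_idx] - 1e-9) {
      if (has_plastic) {
        const Pop& pre = pops[plastic_pre - 1];
        const Pop& post = pops[plastic_post - 1];
        NumericMatrix blocks(pre.nclust, post.nclust);
        for (int j = 0; j < n_pre; ++j) {
          const double* col = Pw + (size_t)j * n_post;
          const int cj = pre.cluster[j];
          for (int i = 0; i < n_post; ++i)
            blocks(cj, post.cluster[i]) += col[i];
        }
        snapshots[snap_idx] = List::create(
          _["t"] = snapshot_times[snap_idx], _["blocks"] = blocks);
      } else {
        snapshots[snap_idx] = List::create(
          _["t"] = snapshot_times[snap_idx], _["blocks"] = R_NilValue);
      }
      ++snap_idx;
    }
  }

  // ---- package results -----------------------------------------------------
  List state_out(P);
  for (int p = 0; p < P; ++p) {
    Pop& pp = pops[p];
    state_out[p] = List::create(
      _["V"] = wrap(pp.V), _["a"] = wrap(pp.a), _["vt"] = wrap(pp.vt),
      _["ref_until"] = wrap(pp.ref_until), _["last_spike"] = wrap(pp.last_spike),
      _["eEd"] = wrap(pp.eEd), _["eEr"] = wrap(pp.eEr),
      _["eId"] = wrap(pp.eId), _["eIr"] = wrap(pp.eIr),
      _["pendE"] = wrap(pp.pendE), _["pendI"] = wrap(pp.pendI));
  }
  state_out.attr("shared") = NumericVector::create(sh_d, sh_r, pend_sh);

  return List::create(
    _["spike_pop"] = wrap(sp_pop),
    _["spike_neuron"] = wrap(sp_neuron),
    _["spike_time"] = wrap(sp_time),
    _["W_plastic"] = has_plastic ? (SEXP)Pmat : R_NilValue,
    _["w_stp"] = has_stp ? (SEXP)wrap(wstp) : R_NilValue,
    _["snapshots"] = snapshots,
    _["state"] = state_out,
    _["t_end"] = t0 + n_steps * dt);
}
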