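// Branched-cable integrator: theta-method (backward Euler / Crank-Nicolson)
// with one Hines tree solve per step and Rush-Larsen exponential gate updates.
// Units: mV, ms, nA, uS, nF (uS * mV = nA; nF * mV / ms = nA).

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>

using namespace Rcpp;

namespace {

struct GateTab {
  int exponent;
  std::vector<double> minf;
  std::vector<double> edt;  // exp(-dt/tau(V))
};

const double V_LO = -150.0, V_HI = 80.0, DV = 0.05;

inline int vindex(double v) {
  if (v < V_LO) v = V_LO;
  if (v > V_HI) v = V_HI;
  return (int)((v - V_LO) / DV + 0.5);
}

inline double ipow(double x, int n) {
  double r = 1.0;
  for (int i = 0; i < n; ++i) r *= x;
  return r;
}

}  // namespace

// [[Rcpp::export(name = ".run_cable_cpp")]]
List run_cable_cpp(IntegerVector parent, NumericVector cap_nF,
                   NumericVector g_leak_uS, NumericVector e_leak,
                   NumericVector g_axial_uS, List channels,
                   NumericMatrix synapses, List syn_events,
                   NumericMatrix stimuli, double dt, double duration,
                   double v_init, IntegerVector record, bool clamp,
                   double v_hold, bool record_current, bool check_residual,
                   double theta) {
  const int N = parent.size();
  const int n_steps = (int)std::lround(duration / dt);
  const int NV = (int)((V_HI - V_LO) / DV) + 2;

  // ---- channel setup: per channel, active compartments + gate tables ----
  const int n_chan = channels.size();
  std::vector<std::vector<int> > chan_comps(n_chan);
  std::vector<std::vector<double> > chan_gbar(n_chan);
  std::vector<double> chan_erev(n_chan);
  std::vector<std::vector<GateTab> > chan_gates(n_chan);
  std::vector<std::vector<std::vector<double> > > gate_state(n_chan);

  for (int c = 0; c < n_chan; ++c) {
    List ch = channels[c];
    NumericVector gbar = ch["gbar_uS"];
    chan_erev[c] = as<double>(ch["e_rev"]);
    for (int i = 0; i < N; ++i) {
      if (gbar[i] > 0) {
        chan_comps[c].push_back(i);
        chan_gbar[c].push_back(gbar[i]);
      }
    }
    List gates = ch["gates"];
    for (int g = 0; g < gates.size(); ++g) {
      NumericVector p = gates[g];
      // p: exponent, vhalf, k, tau_min, tau_amp, tau_vhalf, tau_k1, tau_k2
      GateTab gt;
      gt.exponent = (int)p[0];
      gt.minf.resize(NV);
      gt.edt.resize(NV);
      for (int iv = 0; iv < NV; ++iv) {
        double v = V_LO + iv * DV;
        gt.minf[iv] = 1.0 / (1.0 + std::exp(-(v - p[1]) / p[2]));
        double tau = p[3];
        if (p[4] != 0.0)
          tau += p[4] / (std::exp((v - p[5]) / p[6]) + std::exp(-(v - p[5]) / p[7]));
        gt.edt[iv] = std::exp(-dt / tau);
      }
      chan_gates[c].push_back(gt);
    }
    // initialize states at steady state for v_init
    gate_state[c].resize(chan_gates[c].size());
    int iv0 = vindex(v_init);
    for (size_t g = 0; g < chan_gates[c].size(); ++g)
      gate_state[c][g].assign(chan_comps[c].size(), chan_gates[c][g].minf[iv0]);
  }

  // ---- synapse setup ----
  const int n_syn = synapses.nrow();
  std::vector<int> syn_comp(n_syn);
  std::vector<double> syn_erev(n_syn), syn_g(n_syn), syn_ea(n_syn),
      syn_eb(n_syn), syn_norm(n_syn), syn_A(n_syn, 0.0), syn_B(n_syn, 0.0),
      syn_mg(n_syn);
  std::vector<bool> syn_has_mg(n_syn);
  for (int s = 0; s < n_syn; ++s) {
    syn_comp[s] = (int)synapses(s, 0);
    syn_erev[s] = synapses(s, 1);
    syn_g[s] = synapses(s, 2);
    double tr = synapses(s, 3), td = synapses(s, 4);
    syn_ea[s] = std::exp(-dt / tr);
    syn_eb[s] = std::exp(-dt / td);
    double tp = std::log(td / tr) * tr * td / (td - tr);
    syn_norm[s] = 1.0 / (std::exp(-tp / td) - std::exp(-tp / tr));
    syn_has_mg[s] = synapses(s, 5) != 0.0;
    syn_mg[s] = synapses(s, 6);
  }
  // flatten events to (step, synapse), sorted by step; event at time te takes
  // effect at the first grid time >= te
  std::vector<std::pair<int, int> > events;
  for (int s = 0; s < n_syn; ++s) {
    NumericVector tv = syn_events[s];
    for (int k = 0; k < tv.size(); ++k) {
      int step = (int)std::ceil(tv[k] / dt - 1e-9);
      if (step < 1) step = 1;
      if (step <= n_steps) events.push_back(std::make_pair(step, s));
    }
  }
  std::sort(events.begin(), events.end());

  // ---- stimuli ----
  const int n_stim = stimuli.nrow();

  // ---- state and workspace ----
  std::vector<double> V(N, v_init), d(N), rhs(N), gtot(N), gesum(N), istim(N);
  if (clamp) V[0] = v_hold;
  const int n_rec = record.size();
  NumericMatrix out(n_steps + 1, n_rec);
  NumericVector iclamp(record_current ? (n_steps + 1) : 0);
  for (int r = 0; r < n_rec; ++r) out(0, r) = V[record[r]];

  // children of root (for clamp current)
  std::vector<int> root_children;
  for (int i = 1; i < N; ++i)
    if (parent[i] == 0) root_children.push_back(i);

  double max_resid = 0.0;
  size_t ev_ptr = 0;
  std::vector<double> d_save, rhs_save;  // for residual check
  if (check_residual) { d_save.resize(N); rhs_save.resize(N); }

  for (int n = 1; n <= n_steps; ++n) {
    double t_new = n * dt;

    // synaptic state decay + event increments effective at t_new
    for (int s = 0; s < n_syn; ++s) {
      syn_A[s] *= syn_ea[s];
      syn_B[s] *= syn_eb[s];
    }
    while (ev_ptr < events.size() && events[ev_ptr].first == n) {
      int s = events[ev_ptr].second;
      syn_A[s] += 1.0;
      syn_B[s] += 1.0;
      ++ev_ptr;
    }

    // accumulate conductances
    for (int i = 0; i < N; ++i) {
      gtot[i] = g_leak_uS[i];
      gesum[i] = g_leak_uS[i] * e_leak[i];
      istim[i] = 0.0;
    }
    // gates: Rush-Larsen update using V at start of step, then conductance
    for (int c = 0; c < n_chan; ++c) {
      const std::vector<int>& comps = chan_comps[c];
      const size_t ng = chan_gates[c].size();
      for (size_t j = 0; j < comps.size(); ++j) {
        int i = comps[j];
        int iv = vindex(V[i]);
        double gfac = 1.0;
        for (size_t g = 0; g < ng; ++g) {
          const GateTab& gt = chan_gates[c][g];
          double m = gate_state[c][g][j];
          m = gt.minf[iv] + (m - gt.minf[iv]) * gt.edt[iv];
          gate_state[c][g][j] = m;
          gfac *= ipow(m, gt.exponent);
        }
        double g_uS = chan_gbar[c][j] * gfac;
        gtot[i] += g_uS;
        gesum[i] += g_uS * chan_erev[c];
      }
    }
    // synapses (conductance at t_new; Mg factor lagged to V at start of step)
    for (int s = 0; s < n_syn; ++s) {
      double g = syn_g[s] * syn_norm[s] * (syn_B[s] - syn_A[s]);
      if (g <= 0) continue;
      if (syn_has_mg[s])
        g /= 1.0 + (syn_mg[s] / 3.57) * std::exp(-0.062 * V[syn_comp[s]]);
      gtot[syn_comp[s]] += g;
      gesum[syn_comp[s]] += g * syn_erev[s];
    }
    // current steps active on (onset, onset+dur]
    for (int k = 0; k < n_stim; ++k) {
      if (t_new > stimuli(k, 2) && t_new <= stimuli(k, 2) + stimuli(k, 3))
        istim[(int)stimuli(k, 0)] += stimuli(k, 1);
    }

    // assemble theta-method system
    for (int i = 0; i < N; ++i) {
      double axial = 0.0, axial_flux = 0.0;
      if (parent[i] >= 0) {
        axial += g_axial_uS[i];
        axial_flux += g_axial_uS[i] * (V[i] - V[parent[i]]);
      }
      d[i] = cap_nF[i] / dt + theta * (gtot[i] + axial);
      rhs[i] = cap_nF[i] / dt * V[i] + gesum[i] + istim[i] -
               (1.0 - theta) * (gtot[i] * V[i] + axial_flux);
    }
    // add child couplings to diagonals and explicit flux
    for (int i = 1; i < N; ++i) {
      int p = parent[i];
      d[p] += theta * g_axial_uS[i];
      rhs[p] -= (1.0 - theta) * g_axial_uS[i] * (V[p] - V[i]);
    }
    if (check_residual) {
      for (int i = 0; i < N; ++i) { d_save[i] = d[i]; rhs_save[i] = rhs[i]; }
    }

    // Hines elimination (children are always after parents)
    for (int i = N - 1; i >= 1; --i) {
      int p = parent[i];
      double a = theta * g_axial_uS[i];
      if (clamp && p == 0) continue;  // root fixed; child solved in back-sub
      double f = a / d[i];
      d[p] -= f * a;
      rhs[p] += f * rhs[i];
    }
    if (clamp) {
      V[0] = v_hold;
    } else {
      V[0] = rhs[0] / d[0];
    }
    for (int i = 1; i < N; ++i) {
      double a = theta * g_axial_uS[i];
      V[i] = (rhs[i] + a * V[parent[i]]) / d[i];
    }

    if (check_residual) {
      // residual of the assembled symmetric system A V - b (KCL at every
      // node: axial currents balance capacitive + ionic + injected current)
      for (int i = (clamp ? 1 : 0); i < N; ++i) {
        double av = d_save[i] * V[i];
        if (parent[i] >= 0) av -= theta * g_axial_uS[i] * V[parent[i]];
        for (int j = 1; j < N; ++j)
          if (parent[j] == i) av -= theta * g_axial_uS[j] * V[j];
        double r = std::fabs(av - rhs_save[i]);
        if (r > max_resid) max_resid = r;
      }
    }

    bool bad = false;
    for (int r = 0; r < n_rec; ++r) {
      double v = V[record[r]];
      if (!std::isfinite(v)) bad = true;
      out(n, r) = v;
    }
    if (!std::isfinite(V[0])) bad = true;
    if (bad) stop("numerical failure (non-finite voltage) at t = %.3f ms", t_new);

    if (record_current) {
      // electrode current required to hold the root at v_hold
      double iel = gtot[0] * V[0] - gesum[0] - istim[0];
      for (size_t rc = 0; rc < root_children.size(); ++rc) {
        int cidx = root_children[rc];
        iel += g_axial_uS[cidx] * (V[0] - V[cidx]);
      }
      iclamp[n] = iel;
    }
  }

  List ret = List::create(_["voltages"] = out,
                          _["dt"] = dt,
                          _["max_residual"] = max_resid);
  if (record_current) {
    if (n_steps >= 1) iclamp[0] = iclamp[1];
    ret["clamp_current"] = iclamp;
  }
  return ret;
}
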