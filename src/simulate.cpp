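// Conductance-based compartmental network integrator.
//
// Each cell is a tree of passive compartments (exponential-Euler update, which
// is exact for the piecewise-constant conductances used here); spikes are
// threshold-reset events at the soma.  Synapses are difference-of-exponentials
// conductances, NMDA gated by a Jahr-Stevens magnesium block.  An online,
// potentiation-only LTP rule strengthens plastic synapses on pre/post
// coincidences.  Everything is deterministic given the (pre-generated) drive
// spike trains.

#include <Rcpp.h>
#include <deque>
#include <vector>
#include <cmath>

using namespace Rcpp;

static inline double nmda_gate_c(double v, double mg) {
  // Jahr & Stevens style sigmoidal Mg2+ block, [Mg] in mM, v in mV.
  return 1.0 / (1.0 + (mg / 3.57) * std::exp(-0.062 * v));
}

// [[Rcpp::export]]
NumericVector nmda_gating_cpp(NumericVector v, double mg) {
  int n = v.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    if (!R_finite(v[i])) stop("nmda_gating: non-finite voltage");
    out[i] = nmda_gate_c(v[i], mg);
  }
  return out;
}

// [[Rcpp::export]]
List simulate_network_cpp(int n_cells, int n_comp,
                          NumericVector cm, NumericVector gl, NumericVector el,
                          NumericVector ga, IntegerVector parent,
                          NumericVector thr, NumericVector vreset,
                          NumericVector refr,
                          IntegerVector syn_pre, IntegerVector syn_post,
                          IntegerVector syn_comp, IntegerVector syn_rec,
                          NumericVector syn_w, NumericVector syn_gmax,
                          NumericVector syn_taur, NumericVector syn_taud,
                          NumericVector syn_erev, IntegerVector syn_delay,
                          LogicalVector syn_active, LogicalVector syn_plastic,
                          List drive_steps,
                          double ltp_lr, double ltp_ceiling, double ltp_window,
                          double dt, int n_steps, double mg_conc,
                          NumericVector step_current) {
  const int n_syn = syn_pre.size();
  const int n_state = n_cells * n_comp;

  std::vector<double> V(n_state);
  for (int c = 0; c < n_cells; ++c)
    for (int k = 0; k < n_comp; ++k) V[c * n_comp + k] = el[c];

  // synapse kinetic state and constants
  std::vector<double> sa(n_syn, 0.0), sb(n_syn, 0.0);
  std::vector<double> fd(n_syn), fr(n_syn), norm(n_syn), w(n_syn);
  for (int s = 0; s < n_syn; ++s) {
    fd[s] = std::exp(-dt / syn_taud[s]);
    fr[s] = std::exp(-dt / syn_taur[s]);
    double tp = syn_taud[s] * syn_taur[s] / (syn_taud[s] - syn_taur[s]) *
                std::log(syn_taud[s] / syn_taur[s]);
    norm[s] = 1.0 / (std::exp(-tp / syn_taud[s]) - std::exp(-tp / syn_taur[s]));
    w[s] = syn_w[s];
  }

  // adjacency: outgoing synapses per cell, plastic synapses per post cell
  std::vector<std::vector<int>> outgoing(n_cells), plastic_on(n_cells);
  for (int s = 0; s < n_syn; ++s) {
    if (!syn_active[s]) continue;
    if (syn_pre[s] >= 0) outgoing[syn_pre[s]].push_back(s);
    if (syn_plastic[s]) plastic_on[syn_post[s]].push_back(s);
  }

  // pending recurrent arrivals and drive-train pointers
  std::vector<std::deque<int>> pending(n_syn);
  std::vector<std::vector<int>> dsteps(n_syn);
  std::vector<int> dptr(n_syn, 0);
  for (int s = 0; s < n_syn; ++s) {
    if (drive_steps[s] != R_NilValue) {
      IntegerVector v = drive_steps[s];
      dsteps[s].assign(v.begin(), v.end());
    }
  }

  // presynaptic arrival-time log (for the LTP coincidence count)
  std::vector<std::vector<double>> arrivals(n_syn);
  std::vector<int> aptr(n_syn, 0);

  std::vector<std::vector<double>> spikes(n_cells);
  std::vector<double> refr_until(n_cells, -1e18);

  NumericMatrix vtrace(n_steps, n_cells);

  const int cur_cell = (int)step_current[0];
  const int cur_comp = (int)step_current[1];
  const double cur_amp = step_current[2], cur_on = step_current[3],
               cur_off = step_current[4];

  std::vector<double> Gacc(n_state), GEacc(n_state), Vnew(n_state);

  for (int step = 0; step < n_steps; ++step) {
    const double t = step * dt;
    const double tnext = (step + 1) * dt;
    std::fill(Gacc.begin(), Gacc.end(), 0.0);
    std::fill(GEacc.begin(), GEacc.end(), 0.0);

    // synaptic conductances
    for (int s = 0; s < n_syn; ++s) {
      if (!syn_active[s]) continue;
      sa[s] *= fd[s];
      sb[s] *= fr[s];
      // drive arrivals scheduled for this step
      while (dptr[s] < (int)dsteps[s].size() &&
             dsteps[s][dptr[s]] + syn_delay[s] <= step) {
        if (dsteps[s][dptr[s]] + syn_delay[s] == step) {
          sa[s] += 1.0;
          sb[s] += 1.0;
          arrivals[s].push_back(t);
        }
        ++dptr[s];
      }
      // recurrent arrivals
      while (!pending[s].empty() && pending[s].front() == step) {
        pending[s].pop_front();
        sa[s] += 1.0;
        sb[s] += 1.0;
        arrivals[s].push_back(t);
      }
      double g = w[s] * syn_gmax[s] * norm[s] * (sa[s] - sb[s]);
      if (g <= 0.0) continue;
      int idx = syn_post[s] * n_comp + (syn_comp[s] - 1);
      if (syn_rec[s] == 1) g *= nmda_gate_c(V[idx], mg_conc);
      Gacc[idx] += g;
      GEacc[idx] += g * syn_erev[s];
    }

    // axial coupling (explicit in the neighbour voltage)
    for (int c = 0; c < n_cells; ++c) {
      for (int k = 0; k < n_comp; ++k) {
        int i = c * n_comp + k;
        int p = parent[k];
        if (p < 0) continue;
        int ip = c * n_comp + p;
        double g = ga[c];
        Gacc[i] += g;
        GEacc[i] += g * V[ip];
        Gacc[ip] += g;
        GEacc[ip] += g * V[i];
      }
    }

    // membrane update (exponential Euler)
    for (int c = 0; c < n_cells; ++c) {
      for (int k = 0; k < n_comp; ++k) {
        int i = c * n_comp + k;
        double G = gl[c] + Gacc[i];
        double num = gl[c] * el[c] + GEacc[i];
        if (c == cur_cell && k == cur_comp && t >= cur_on && t < cur_off)
          num += cur_amp;
        double Eeff = num / G;
        double vn = Eeff + (V[i] - Eeff) * std::exp(-G * dt / cm[c]);
        if (!std::isfinite(vn))
          stop("integration blow-up: cell %d compartment %d at t = %f ms",
               c + 1, k + 1, t);
        Vnew[i] = vn;
      }
    }
    std::swap(V, Vnew);

    // threshold-reset spiking at the soma
    for (int c = 0; c < n_cells; ++c) {
      int i = c * n_comp;
      if (V[i] >= thr[c] && tnext >= refr_until[c]) {
        spikes[c].push_back(tnext);
        refr_until[c] = tnext + refr[c];
        V[i] = vreset[c];
        for (int s : outgoing[c]) pending[s].push_back(step + syn_delay[s]);
        // potentiation-only LTP: each presynaptic arrival within the
        // coincidence window preceding the postsynaptic spike adds
        // lr * (1 - w / ceiling), saturating at the ceiling.
        if (ltp_lr > 0.0) {
          for (int s : plastic_on[c]) {
            const std::vector<double> &arr = arrivals[s];
            while (aptr[s] < (int)arr.size() && arr[aptr[s]] < tnext - ltp_window)
              ++aptr[s];
            int j = aptr[s];
            while (j < (int)arr.size() && arr[j] <= tnext) {
              w[s] += ltp_lr * (1.0 - w[s] / ltp_ceiling);
              if (w[s] > ltp_ceiling) w[s] = ltp_ceiling;
              ++j;
            }
          }
        }
      }
      vtrace(step, c) = V[i];
    }
  }

  List spk(n_cells);
  for (int c = 0; c < n_cells; ++c) spk[c] = NumericVector(spikes[c].begin(), spikes[c].end());
  return List::create(_["voltage"] = vtrace, _["spikes"] = spk,
                      _["final_weights"] = NumericVector(w.begin(), w.end()));
}
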