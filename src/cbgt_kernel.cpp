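#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Single-trial simulation of the spiking CBGT network.
//
// Neurons are integrate-and-fire-or-burst units,
//   C dV/dt = -gL (V - VL) - gT h H(V - Vh) (V - VT) - Isyn,
// with h decaying (tau_h-) above Vh and recovering toward 1 (tau_h+) below,
// spike emission at Vb and reset to Vr.  Synaptic currents are
//   Isyn = gA (V - VE) + gN s B(V) (V - VE) + gG (V - VI),
// with the NMDA voltage gate B(V) = 1 / (1 + exp(-0.062 V)/3.57).  AMPA and
// GABA_A gating is linear (unit increment per arriving spike, exponential
// decay), so the conductance-weighted sum over afferents is tracked as a
// single per-neuron state.  NMDA gating saturates per synapse
// (ds/dt = alpha (1 - s) sum_j delta(t - t_j) - s/tau); afferents of one
// projection are pooled per target with capacity equal to the target's
// in-degree (S += alpha (1 - S/n_in) per spike), which is exact for
// homogeneous per-synapse gates.  Spike delivery honours the transmission
// delay rounded up to whole integration steps.  Background and stimulus
// drives are independent Poisson trains per neuron through AMPA conductances,
// generated by exponential waiting times from R's RNG (so trials are
// reproducible under set.seed()).
//
// Integration is forward Euler at dt (default 0.05 ms); gating decays use
// exact exponential factors.  The trial ends at the first 1-ms boundary
// after stimulus onset at which a decision population's firing rate
// (spike count in a sliding window, per neuron, in Hz) crosses the
// threshold, or at t_max.

struct Proj {
  int src, tgt;            // population indices
  int receptor;            // 0 AMPA, 1 NMDA, 2 GABA
  double g;                // conductance (nS)
  const int *adj;          // global target ids, concatenated per src neuron
  const int *ptr;          // offsets, length n_src + 1
  std::vector<double> s;   // NMDA pooled gating per local target
  std::vector<double> cap; // NMDA capacity (in-degree) per local target
};

// [[Rcpp::export]]
List cbgt_trial_cpp(List net, NumericVector stim_rate_hz, double stim_g,
                    double stim_onset_ms, List opts) {
  List pops = net["pops"];
  List projections = net["projections"];
  NumericVector bg_rate = net["bg_rate_hz"];   // per population, per neuron
  NumericVector bg_g = net["bg_g"];

  const double dt = as<double>(opts["dt_ms"]);
  const double t_max = as<double>(opts["t_max_ms"]);
  const double delay_ms = as<double>(opts["delay_ms"]);
  const double thr_hz = as<double>(opts["threshold_hz"]);
  const int win_ms = as<int>(opts["rate_window_ms"]);
  IntegerVector decide_pops = opts["decide_pops"];  // 0-based, {L, R}
  const double tau_ampa = as<double>(opts["tau_ampa"]);
  const double tau_gaba = as<double>(opts["tau_gaba"]);
  const double tau_nmda = as<double>(opts["tau_nmda"]);
  const double alpha = as<double>(opts["alpha_nmda"]);
  const double VE = as<double>(opts["VE"]);
  const double VI = as<double>(opts["VI"]);
  const double ramp_ms = as<double>(opts["stim_ramp_ms"]);

  const int n_pops = pops.size();
  std::vector<int> offset(n_pops + 1, 0);
  std::vector<NumericVector> prm(n_pops);
  for (int p = 0; p < n_pops; ++p) {
    List pop = pops[p];
    prm[p] = as<NumericVector>(pop["params"]);
    offset[p + 1] = offset[p] + as<int>(pop["n"]);
  }
  const int N = offset[n_pops];
  std::vector<int> pop_of(N);
  for (int p = 0; p < n_pops; ++p)
    for (int i = offset[p]; i < offset[p + 1]; ++i) pop_of[i] = p;

  // per-neuron parameter pointers (C,gL,VL,Vh,VT,gT,tauh_minus,tauh_plus,Vb,Vr)
  enum { P_C, P_GL, P_VL, P_VH, P_VT, P_GT, P_THM, P_THP, P_VB, P_VR };

  std::vector<Proj> proj;
  std::vector<std::vector<int>> out_of(n_pops);
  for (int j = 0; j < projections.size(); ++j) {
    List pj = projections[j];
    Proj pr;
    pr.src = as<int>(pj["src"]);
    pr.tgt = as<int>(pj["tgt"]);
    pr.receptor = as<int>(pj["receptor"]);
    pr.g = as<double>(pj["g"]);
    IntegerVector adj = pj["adj"], ptr = pj["ptr"];
    pr.adj = INTEGER(adj);
    pr.ptr = INTEGER(ptr);
    int n_tgt = offset[pr.tgt + 1] - offset[pr.tgt];
    if (pr.receptor == 1) {
      pr.s.assign(n_tgt, 0.0);
      NumericVector indeg = pj["indeg"];
      pr.cap.assign(indeg.begin(), indeg.end());
    }
    out_of[pr.src].push_back((int)proj.size());
    proj.push_back(std::move(pr));
    // keep R vectors alive: they are owned by `net`, still referenced
  }

  RNGScope scope;

  // state
  std::vector<double> V(N), h(N, 0.5), gA(N, 0.0), gG(N, 0.0);
  for (int i = 0; i < N; ++i) {
    const NumericVector &q = prm[pop_of[i]];
    V[i] = q[P_VL] + unif_rand() * (q[P_VB] - 2.0 - q[P_VL]);
  }

  // decay factors
  const double dA = std::exp(-dt / tau_ampa);
  const double dG = std::exp(-dt / tau_gaba);
  const double dN = std::exp(-dt / tau_nmda);

  // NMDA voltage gate lookup table over [-120, 20] mV
  const double tab_lo = -120.0, tab_hi = 20.0, tab_step = 0.1;
  const int tab_n = (int)((tab_hi - tab_lo) / tab_step) + 2;
  std::vector<double> Btab(tab_n);
  for (int i = 0; i < tab_n; ++i) {
    double v = tab_lo + i * tab_step;
    Btab[i] = 1.0 / (1.0 + std::exp(-0.062 * v) / 3.57);
  }
  auto Bgate = [&](double v) {
    if (v <= tab_lo) return Btab[0];
    if (v >= tab_hi) return Btab[tab_n - 1];
    return Btab[(int)((v - tab_lo) / tab_step)];
  };

  // Poisson background: next event time per neuron
  std::vector<double> next_bg(N, 1e18), bg_gap(N, 0.0), bgg(N, 0.0);
  for (int i = 0; i < N; ++i) {
    double r = bg_rate[pop_of[i]];            // Hz
    if (r > 0) {
      bg_gap[i] = 1000.0 / r;                 // mean gap in ms
      next_bg[i] = -std::log(unif_rand()) * bg_gap[i];
      bgg[i] = bg_g[pop_of[i]];
    }
  }
  // stimulus trains (start at onset)
  std::vector<double> next_st(N, 1e18), st_gap(N, 0.0);
  for (int i = 0; i < N; ++i) {
    double r = stim_rate_hz[pop_of[i]];
    if (r > 0) {
      st_gap[i] = 1000.0 / r;
      next_st[i] = stim_onset_ms - std::log(unif_rand()) * st_gap[i];
    }
  }

  // spike delay ring buffer
  const int delay_steps = std::max(1, (int)std::ceil(delay_ms / dt - 1e-9));
  std::vector<std::vector<int>> ring(delay_steps + 1);
  int ring_pos = 0;

  const int n_bins = (int)std::ceil(t_max);
  IntegerMatrix spike_bins(n_pops, n_bins);   // spike counts per pop per ms
  const int steps_per_ms = (int)std::round(1.0 / dt);
  const int n_steps = (int)std::round(t_max / dt);

  // sliding decision windows
  std::vector<std::vector<int>> win_counts(2, std::vector<int>(win_ms, 0));
  int choice = 0;          // 0 none, 1 L, 2 R
  double rt = NA_REAL;

  int bin = 0;
  double t = 0.0;
  std::vector<double> gNB(N, 0.0);
  for (int step = 0; step < n_steps; ++step) {
    t = (step + 1) * dt;
    // deliver spikes scheduled for this step
    std::vector<int> &due = ring[ring_pos];
    for (size_t si = 0; si < due.size(); ++si) {
      int gsrc = due[si];
      int p = pop_of[gsrc];
      int local = gsrc - offset[p];
      const std::vector<int> &outs = out_of[p];
      for (size_t oi = 0; oi < outs.size(); ++oi) {
        Proj &pr = proj[outs[oi]];
        const int lo = pr.ptr[local], hi = pr.ptr[local + 1];
        if (pr.receptor == 0) {
          for (int k = lo; k < hi; ++k) gA[pr.adj[k]] += pr.g;
        } else if (pr.receptor == 2) {
          for (int k = lo; k < hi; ++k) gG[pr.adj[k]] += pr.g;
        } else {
          const int toff = offset[pr.tgt];
          for (int k = lo; k < hi; ++k) {
            int lt = pr.adj[k] - toff;
            pr.s[lt] += alpha * (1.0 - pr.s[lt] / pr.cap[lt]);
          }
        }
      }
    }
    due.clear();

    // background + stimulus arrivals
    for (int i = 0; i < N; ++i) {
      while (next_bg[i] <= t) {
        gA[i] += bgg[i];
        next_bg[i] += -std::log(unif_rand()) * bg_gap[i];
      }
      while (next_st[i] <= t) {
        // linear onset ramp: thin the full-rate train by the ramp fraction
        double frac = ramp_ms > 0
          ? std::min((next_st[i] - stim_onset_ms) / ramp_ms, 1.0) : 1.0;
        if (frac >= 1.0 || unif_rand() < frac) gA[i] += stim_g;
        next_st[i] += -std::log(unif_rand()) * st_gap[i];
      }
    }

    // NMDA conductance accumulation and gating decay
    std::fill(gNB.begin(), gNB.end(), 0.0);
    for (size_t j = 0; j < proj.size(); ++j) {
      Proj &pr = proj[j];
      if (pr.receptor != 1) continue;
      const int toff = offset[pr.tgt];
      const int n_tgt = (int)pr.s.size();
      for (int k = 0; k < n_tgt; ++k) {
        pr.s[k] *= dN;
        gNB[toff + k] += pr.g * pr.s[k];
      }
    }

    // membrane update, spike detection; spikes emitted this step are
    // delivered delay_steps later
    int push_slot = (ring_pos + delay_steps) % (delay_steps + 1);
    for (int i = 0; i < N; ++i) {
      const NumericVector &q = prm[pop_of[i]];
      double v = V[i];
      double Isyn = gA[i] * (v - VE) + gNB[i] * Bgate(v) * (v - VE) +
        gG[i] * (v - VI);
      double IT = 0.0;
      if (q[P_GT] > 0.0) {
        if (v >= q[P_VH]) {
          IT = q[P_GT] * h[i] * (v - q[P_VT]);
          h[i] *= std::exp(-dt / q[P_THM]);
        } else {
          h[i] = 1.0 + (h[i] - 1.0) * std::exp(-dt / q[P_THP]);
        }
      }
      v += dt / (1000.0 * q[P_C]) * (-q[P_GL] * (v - q[P_VL]) - IT - Isyn);
      if (v >= q[P_VB]) {
        v = q[P_VR];
        ring[push_slot].push_back(i);
        spike_bins(pop_of[i], bin) += 1;
      }
      V[i] = v;
      gA[i] *= dA;
      gG[i] *= dG;
    }
    ring_pos = (ring_pos + 1) % (delay_steps + 1);

    // end of a 1-ms bin: decision check
    if ((step + 1) % steps_per_ms == 0) {
      for (int d = 0; d < 2; ++d) {
        int p = decide_pops[d];
        win_counts[d][bin % win_ms] = spike_bins(p, bin);
      }
      if (t >= stim_onset_ms && bin + 1 >= win_ms) {
        double rate_d[2];
        for (int d = 0; d < 2; ++d) {
          int p = decide_pops[d];
          int cnt = 0;
          for (int w = 0; w < win_ms; ++w) cnt += win_counts[d][w];
          int n_p = offset[p + 1] - offset[p];
          rate_d[d] = cnt / (n_p * win_ms * 1e-3);
        }
        // if both channels cross within the same 1-ms bin, the one with
        // the higher rate wins; exact ties are broken at random
        if (rate_d[0] >= thr_hz || rate_d[1] >= thr_hz) {
          if (rate_d[0] > rate_d[1]) choice = 1;
          else if (rate_d[1] > rate_d[0]) choice = 2;
          else choice = (unif_rand() < 0.5) ? 1 : 2;
          rt = t;
        }
      }
      ++bin;
      if (choice != 0) break;
    }
  }

  return List::create(_["choice"] = choice, _["rt_ms"] = rt,
                      _["spike_bins"] = spike_bins, _["n_bins_filled"] = bin,
                      _["t_end"] = t);
}
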