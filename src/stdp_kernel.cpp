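#include <Rcpp.h>
#include <vector>
#include <deque>
#include <cmath>
using namespace Rcpp;

// Reduced two-channel striatal learning network with dopamine-modulated
// STDP and Q-learning.
//
// Four MSN populations (dMSN/iMSN x L/R channels) of exponential
// integrate-and-fire neurons.  Each neuron receives one cortical "daughter"
// spike train thinned from its channel's oscillatory-Poisson mother train
// with transfer probability p_D (dMSN) or p_I (iMSN), through a plastic
// AMPA-like conductance w (nS).  Each synapse carries an eligibility trace
// updated by a pair-based STDP rule on nearest-neighbour pre/post spike
// pairs (pre-before-post potentiates eligibility, post-before-pre
// depresses it) with exponential decay between events.
//
// Action selection: the first channel to accumulate three distinct dMSN
// spikes within the selection window is chosen; an iMSN spike in a channel
// cancels that channel's most recent counted dMSN spike.  On selection a
// reward is drawn (Bernoulli(p_ch), or a fixed level), dopamine is set to
// the reward prediction error r - max(Q_L, Q_R), Q-learning updates the
// chosen action's value, and every synapse's weight moves by
// gain * DA * eligibility (dMSNs have a larger phasic-DA gain than iMSNs,
// whose update has opposite sign, i.e. phasic dopamine depresses
// cortico-iMSN synapses).  Counters reset and cortical input is silenced
// for 50 ms after each selection.  Weights are clipped to [0, w_max].
//
// Integration: fixed-step Euler at dt = 0.01 ms for the membrane (the
// synaptic and eligibility decays use exact exponential factors).

// [[Rcpp::export]]
List stdp_learn_cpp(List cfg) {
  const double dt = as<double>(cfg["dt_ms"]);
  const double T = as<double>(cfg["duration_ms"]);
  const int n_per_pop = as<int>(cfg["n_per_pop"]);
  // EIF membrane
  const double C = as<double>(cfg["C"]), gL = as<double>(cfg["gL"]);
  const double VL = as<double>(cfg["VL"]), VT = as<double>(cfg["VT"]);
  const double DeltaT = as<double>(cfg["DeltaT"]);
  const double Vb = as<double>(cfg["Vb"]), Vr = as<double>(cfg["Vr"]);
  const double VE = as<double>(cfg["VE"]), tau_s = as<double>(cfg["tau_s"]);
  // mother trains
  const double rate0 = as<double>(cfg["mother_rate_hz"]);
  const double mod_depth = as<double>(cfg["osc_depth"]);
  const double mod_freq = as<double>(cfg["osc_freq_hz"]);
  const double pD = as<double>(cfg["pD"]), pI = as<double>(cfg["pI"]);
  // plasticity
  const double A_plus = as<double>(cfg["A_plus"]);
  const double A_minus = as<double>(cfg["A_minus"]);
  const double tau_plus = as<double>(cfg["tau_plus"]);
  const double tau_minus = as<double>(cfg["tau_minus"]);
  const double tau_elig = as<double>(cfg["tau_elig"]);
  const double eta_d = as<double>(cfg["eta_d"]);
  const double eta_i = as<double>(cfg["eta_i"]);
  const double kappa_d = as<double>(cfg["kappa_d"]);
  const double w0 = as<double>(cfg["w0"]), w_max = as<double>(cfg["w_max"]);
  // task
  const double alpha_q = as<double>(cfg["alpha_q"]);
  const double pL = as<double>(cfg["p_L"]), pR = as<double>(cfg["p_R"]);
  const bool fixed_reward = as<bool>(cfg["fixed_reward"]);
  const double rL_fixed = as<double>(cfg["r_L"]);
  const double rR_fixed = as<double>(cfg["r_R"]);
  const double sel_window = as<double>(cfg["select_window_ms"]);
  const int sel_count = as<int>(cfg["select_count"]);
  const double silence_ms = as<double>(cfg["silence_ms"]);
  const double record_every = as<double>(cfg["record_every_ms"]);

  // populations: 0 dMSN_L, 1 iMSN_L, 2 dMSN_R, 3 iMSN_R
  const int n_pops = 4;
  const int N = n_pops * n_per_pop;
  auto pop_of = [&](int i) { return i / n_per_pop; };

  RNGScope scope;
  std::vector<double> V(N), s(N, 0.0), w(N, w0), e(N, 0.0);
  std::vector<double> last_pre(N, -1e9), last_post(N, -1e9);
  std::vector<double> last_e_update(N, 0.0);
  for (int i = 0; i < N; ++i) V[i] = VL + unif_rand() * (VT - VL);

  const double ds = std::exp(-dt / tau_s);

  // eligibility decay applied lazily at event times
  auto decay_e = [&](int i, double t) {
    e[i] *= std::exp(-(t - last_e_update[i]) / tau_elig);
    last_e_update[i] = t;
  };

  // next mother spike per channel (homogeneous-Poisson thinning of an
  // oscillatory rate: draw at peak rate, keep with relative rate)
  const double peak_rate = rate0 * (1.0 + mod_depth);
  double next_mother[2];
  for (int c = 0; c < 2; ++c)
    next_mother[c] = -std::log(unif_rand()) * 1000.0 / peak_rate;

  double Q[2] = {0.0, 0.0};
  double silence_until = -1.0;
  // per-channel deques of counted dMSN spike times
  std::deque<double> counted[2];

  const int n_rec = (int)(T / record_every) + 1;
  NumericMatrix w_traj(n_rec, n_pops);     // mean weight per pop
  NumericMatrix q_traj(n_rec, 2);
  NumericVector rec_time(n_rec);
  int rec_i = 0;
  std::vector<int> spike_count(n_pops, 0);
  std::vector<int> sel_count_ch(2, 0);
  int iwin_suppressed = 0;

  double t = 0.0;
  const long n_steps = (long)std::round(T / dt);
  const long rec_steps = (long)std::round(record_every / dt);
  for (long step = 0; step < n_steps; ++step) {
    t = (step + 1) * dt;

    // mother spikes and thinning to daughters
    for (int c = 0; c < 2; ++c) {
      while (next_mother[c] <= t) {
        double ts = next_mother[c];
        double rel = (1.0 + mod_depth *
                      std::sin(2.0 * M_PI * mod_freq * ts / 1000.0)) /
          (1.0 + mod_depth);
        if (unif_rand() < rel && ts >= silence_until) {
          // deliver to this channel's daughters
          for (int pp = 0; pp < 2; ++pp) {      // 0 dMSN, 1 iMSN
            int pop = 2 * c + pp;
            double p_tr = (pp == 0) ? pD : pI;
            for (int k = 0; k < n_per_pop; ++k) {
              int i = pop * n_per_pop + k;
              if (unif_rand() < p_tr) {
                s[i] += 1.0;
                // STDP: post-before-pre depression of eligibility
                decay_e(i, ts);
                e[i] -= A_minus * std::exp(-(ts - last_post[i]) / tau_minus);
                last_pre[i] = ts;
              }
            }
          }
        }
        next_mother[c] += -std::log(unif_rand()) * 1000.0 / peak_rate;
      }
    }

    // membrane update
    for (int i = 0; i < N; ++i) {
      double v = V[i];
      double expo = (v > VT - 10.0 * DeltaT)
        ? gL * DeltaT * std::exp((v - VT) / DeltaT) : 0.0;
      v += dt / (1000.0 * C) * (-gL * (v - VL) + expo - w[i] * s[i] * (v - VE));
      s[i] *= ds;
      if (v >= Vb) {
        v = Vr;
        int pop = pop_of(i);
        spike_count[pop] += 1;
        // STDP: pre-before-post potentiation
        decay_e(i, t);
        e[i] += A_plus * std::exp(-(t - last_pre[i]) / tau_plus);
        last_post[i] = t;
        int c = pop / 2;
        bool is_d = (pop % 2) == 0;
        if (is_d) {
          counted[c].push_back(t);
        } else if (!counted[c].empty()) {
          counted[c].pop_back();               // iMSN suppresses latest dMSN
          ++iwin_suppressed;
        }
        // purge stale counted spikes, then check selection
        while (!counted[c].empty() && counted[c].front() < t - sel_window)
          counted[c].pop_front();
        if (is_d && (int)counted[c].size() >= sel_count) {
          // action selected
          double r;
          if (fixed_reward) {
            r = (c == 0) ? rL_fixed : rR_fixed;
          } else {
            r = (unif_rand() < ((c == 0) ? pL : pR)) ? 1.0 : 0.0;
          }
          double da = r - std::max(Q[0], Q[1]);
          Q[c] += alpha_q * (r - Q[c]);
          // dMSN synapses are less sensitive to dopamine dips than bursts
          double da_d = (da >= 0.0) ? da : kappa_d * da;
          for (int j = 0; j < N; ++j) {
            decay_e(j, t);
            bool jd = (pop_of(j) % 2) == 0;
            double dw = (jd ? eta_d * da_d : -eta_i * da) * e[j];
            w[j] += dw;
            if (w[j] < 0.0) w[j] = 0.0;
            if (w[j] > w_max) w[j] = w_max;
          }
          counted[0].clear();
          counted[1].clear();
          silence_until = t + silence_ms;
          sel_count_ch[c] += 1;
        }
      }
      V[i] = v;
    }

    if ((step + 1) % rec_steps == 0 && rec_i < n_rec) {
      rec_time[rec_i] = t;
      for (int p = 0; p < n_pops; ++p) {
        double m = 0.0;
        for (int k = 0; k < n_per_pop; ++k) m += w[p * n_per_pop + k];
        w_traj(rec_i, p) = m / n_per_pop;
      }
      q_traj(rec_i, 0) = Q[0];
      q_traj(rec_i, 1) = Q[1];
      ++rec_i;
    }
  }

  NumericVector rates(n_pops);
  for (int p = 0; p < n_pops; ++p)
    rates[p] = spike_count[p] / (n_per_pop * T / 1000.0);

  return List::create(
    _["time_ms"] = rec_time[Range(0, std::max(rec_i - 1, 0))],
    _["w_traj"] = w_traj, _["q_traj"] = q_traj, _["rec_filled"] = rec_i,
    _["mean_rate_hz"] = rates,
    _["n_selections"] = IntegerVector::create(sel_count_ch[0],
                                              sel_count_ch[1]),
    _["n_suppressed"] = iwin_suppressed,
    _["Q_final"] = NumericVector::create(Q[0], Q[1]));
}
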