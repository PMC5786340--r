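#include <Rcpp.h>
#include "ltcc.h"
#include "rng.h"
using namespace Rcpp;

static const char *LTCC_STATE_NAMES[7] = {"C2",   "C1",   "O",   "I1Ca",
                                          "I2Ca", "I1Ba", "I2Ba"};

// [[Rcpp::export(name = ".ltcc_rates_cpp")]]
List ltcc_rates_cpp(double V, double cp, double n_open, List params) {
  LtccParams p = ltcc_params_from_list(params);
  LtccRates r = ltcc_rates(V, cp, n_open, p);
  return List::create(
      _["alpha_eff"] = r.alpha_eff, _["beta"] = r.beta, _["r1_eff"] = r.r1_eff,
      _["r2"] = r.r2, _["s1"] = r.s1, _["s2"] = r.s2, _["s1p"] = r.s1p,
      _["s2p"] = r.s2p, _["k1"] = r.k1, _["k2"] = r.k2, _["k1p"] = r.k1p,
      _["k2p"] = r.k2p, _["k3"] = r.k3, _["k4"] = r.k4, _["k3p"] = r.k3p,
      _["k4p"] = r.k4p, _["k5"] = r.k5, _["k6"] = r.k6, _["k5p"] = r.k5p,
      _["k6p"] = r.k6p, _["gamma1"] = r.gamma1, _["gamma2"] = r.gamma2);
}

// Generator (infinitesimal rate) matrix of the 7-state chain at fixed
// (V, cp, n_open); rows = from-state, row sums are zero.
// [[Rcpp::export(name = ".ltcc_generator_cpp")]]
NumericMatrix ltcc_generator_cpp(double V, double cp, double n_open,
                                 List params) {
  LtccParams p = ltcc_params_from_list(params);
  LtccRates r = ltcc_rates(V, cp, n_open, p);
  NumericMatrix Q(7, 7);
  int targets[4];
  double rates[4];
  for (int s = 0; s < 7; ++s) {
    int ne = ltcc_exits(r, s, targets, rates);
    double tot = 0.0;
    for (int e = 0; e < ne; ++e) {
      Q(s, targets[e]) = rates[e];
      tot += rates[e];
    }
    Q(s, s) = -tot;
  }
  CharacterVector nm(7);
  for (int i = 0; i < 7; ++i) nm[i] = LTCC_STATE_NAMES[i];
  Q.attr("dimnames") = List::create(nm, nm);
  return Q;
}

// [[Rcpp::export(name = ".ltcc_single_current_cpp")]]
NumericVector ltcc_single_current_cpp(NumericVector V, NumericVector cp,
                                      List params) {
  LtccParams p = ltcc_params_from_list(params);
  int n = std::max(V.size(), cp.size());
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = ltcc_single_current(V[i % V.size()], cp[i % cp.size()], p);
  return out;
}

// Stochastic simulation of one cluster of 1..25 channels at (possibly
// time-varying) clamped V and cp.  Per-channel fixed-dt Bernoulli
// transitions; rates evaluated with the open count at the start of the step.
// Returns the n_open trace, per-state occupancy fractions (time average over
// channels), optionally the joint 2-channel occupancy, and final states.
// [[Rcpp::export(name = ".simulate_cluster_cpp")]]
List simulate_cluster_cpp(List params, int n_channels, NumericVector V,
                          NumericVector cp, double dt, int n_steps,
                          int seed, IntegerVector init_states,
                          bool record_joint = false) {
  if (n_channels < 1 || n_channels > 25)
    stop("cluster size must be in [1, 25]");
  LtccParams p = ltcc_params_from_list(params);
  Xoshiro rng;
  rng.seed((uint64_t)seed, 0);

  std::vector<int> st(n_channels, ST_C2);
  if (init_states.size() == n_channels)
    for (int i = 0; i < n_channels; ++i) st[i] = init_states[i];

  IntegerVector n_open_trace(n_steps);
  NumericVector occupancy(7);
  NumericMatrix joint(record_joint ? 7 : 0, record_joint ? 7 : 0);

  int n_open = 0;
  for (int i = 0; i < n_channels; ++i)
    if (st[i] == ST_O) ++n_open;

  int targets[4];
  double rates[4];
  for (int t = 0; t < n_steps; ++t) {
    double Vt = V[t % V.size()];
    double cpt_ = cp[t % cp.size()];
    LtccRates r = ltcc_rates(Vt, cpt_, (double)n_open, p);

    // per-state cumulative transition probabilities for this step
    double cum[7][4];
    int tg[7][4];
    int nex[7];
    for (int s = 0; s < 7; ++s) {
      int ne = ltcc_exits(r, s, targets, rates);
      nex[s] = ne;
      double acc = 0.0;
      for (int e = 0; e < ne; ++e) {
        acc += rates[e] * dt;
        cum[s][e] = acc;
        tg[s][e] = targets[e];
      }
      if (acc >= 0.1)
        stop("dt too large: total exit probability %.3f >= 0.1 per step; "
             "reduce dt (substep)", acc);
    }

    int new_open = n_open;
    for (int i = 0; i < n_channels; ++i) {
      int s = st[i];
      double u = rng.unif();
      int ne = nex[s];
      if (u < cum[s][ne - 1]) {
        int k = 0;
        while (u >= cum[s][k]) ++k;
        int ns = tg[s][k];
        if (s == ST_O) --new_open;
        if (ns == ST_O) ++new_open;
        st[i] = ns;
      }
    }
    n_open = new_open;
    n_open_trace[t] = n_open;
    for (int i = 0; i < n_channels; ++i) occupancy[st[i]] += 1.0;
    if (record_joint && n_channels == 2) joint(st[0], st[1]) += 1.0;
  }

  for (int s = 0; s < 7; ++s)
    occupancy[s] /= (double)n_steps * n_channels;
  if (record_joint && n_channels == 2)
    for (int a = 0; a < 7; ++a)
      for (int b = 0; b < 7; ++b) joint(a, b) /= (double)n_steps;

  IntegerVector fin(n_channels);
  for (int i = 0; i < n_channels; ++i) fin[i] = st[i];
  return List::create(_["n_open"] = n_open_trace, _["occupancy"] = occupancy,
                      _["joint"] = joint, _["final_states"] = fin);
}
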