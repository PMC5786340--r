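#ifndef COOPGATE_LTCC_H
#define COOPGATE_LTCC_H

#include <Rcpp.h>
#include <cmath>

// 7-state Markov L-type Ca channel (Mahajan-topology) with cooperative
// gating factors gamma1 (on the activation rate alpha) and gamma2 (on the
// opening rate r1).  State indices:
//   0 = C2 (deep closed)   1 = C1 (closed)    2 = O (open)
//   3 = I1Ca  4 = I2Ca  (Ca-inactivated)
//   5 = I1Ba  6 = I2Ba  (voltage/Ba-inactivated)
enum LtccState { ST_C2 = 0, ST_C1, ST_O, ST_I1CA, ST_I2CA, ST_I1BA, ST_I2BA };

struct LtccParams {
  // coupling
  double w1, w2, po_x, cp_x;
  // permeation
  double PCa, gamma_i, gamma_o, Cao; // Cao mM, cp uM
  double Fc, Rc, Tc;                 // physical constants
  // Markov rate constants
  double tau_po;   // ms
  double r1, r2;   // 1/ms
  double s1p;      // O -> I1Ba
  double k1p, k2p; // C1 <-> I1Ba
  double k2;       // I1Ca -> C1
  double TBa;      // ms
  double cpt;      // ~cp in f(cp), uM
  double cpminus;  // cp^- in TCa, uM
};

struct LtccRates {
  double alpha_eff, beta;   // C2<->C1 (alpha already multiplied by gamma1)
  double r1_eff, r2;        // C1<->O (r1 multiplied by gamma2)
  double s1, s2, s1p, s2p;  // O<->I1Ca, O<->I1Ba
  double k1, k2, k1p, k2p;  // C1<->I1Ca, C1<->I1Ba
  double k3, k4, k3p, k4p;  // I1<->I2
  double k5, k6, k5p, k6p;  // I2<->C2
  double gamma1, gamma2;
};

inline LtccParams ltcc_params_from_list(const Rcpp::List &l) {
  LtccParams p;
  p.w1 = l["w1"]; p.w2 = l["w2"]; p.po_x = l["po_x"]; p.cp_x = l["cp_x"];
  p.PCa = l["PCa"]; p.gamma_i = l["gamma_i"]; p.gamma_o = l["gamma_o"];
  p.Cao = l["Cao"]; p.Fc = l["F"]; p.Rc = l["R"]; p.Tc = l["T"];
  p.tau_po = l["tau_po"]; p.r1 = l["r1"]; p.r2 = l["r2"];
  p.s1p = l["s1p"]; p.k1p = l["k1p"]; p.k2p = l["k2p"]; p.k2 = l["k2"];
  p.TBa = l["TBa"]; p.cpt = l["cpt"]; p.cpminus = l["cpminus"];
  return p;
}

inline void ltcc_coupling(double n_open, double cp, const LtccParams &p,
                          double &g1, double &g2) {
  double so = 1.0 / (1.0 + std::exp(-15.0 * (n_open / 3.0 - p.po_x)));
  double sc = 1.0 / (1.0 + std::exp(-1.0 * (cp - p.cp_x)));
  g1 = 1.0 + p.w1 * so * sc;
  g2 = 1.0 + p.w2 * so * sc;
}

struct LtccVdep;
inline LtccVdep ltcc_vdep(double V, const LtccParams &p);
inline LtccRates ltcc_rates_fast(const LtccVdep &vd, double cp, double n_open,
                                 const LtccParams &p);

// Full rate set at (V, cp, n_open).  Detailed balance:
//   s2  = s1 (k2/k1) / (r1_eff/r2)   (f(cp) cancels, s2 finite at cp = 0)
//   k4  = k3 (alpha_eff/beta)(k1/k2)(k5/k6)   (f(cp) cancels likewise)
// gamma2 is applied wherever r1 appears, gamma1 wherever alpha appears.
inline LtccRates ltcc_rates(double V, double cp, double n_open,
                            const LtccParams &p);

// Voltage-only parts of the rate set, shared by all clusters at a common
// membrane potential (lattice fast path).
struct LtccVdep {
  double alpha, beta, k3, Pr, Ps, RV, tau_ba, k5p, k6p;
};

inline LtccVdep ltcc_vdep(double V, const LtccParams &p) {
  LtccVdep v;
  double po_inf = 1.0 / (1.0 + std::exp(-V / 8.0));
  v.alpha = po_inf / p.tau_po;
  v.beta = (1.0 - po_inf) / p.tau_po;
  double ex = std::exp(-(V + 40.0) / 3.0);
  v.k3 = ex / (3.0 * (1.0 + ex));
  v.Pr = 1.0 / (1.0 + std::exp((V + 40.0) / 4.0));
  // Ps rises with depolarisation (recovery from Ca/Ba inactivation is fast
  // at the resting potential, ~tens of ms, and suppressed at the plateau)
  v.Ps = 1.0 / (1.0 + std::exp(-(V + 40.0) / 11.32));
  v.RV = 10.0 + 4954.0 * std::exp(V / 15.6);
  v.tau_ba = (v.RV - p.TBa) * v.Pr + p.TBa;
  v.k5p = (1.0 - v.Ps) / v.tau_ba;
  v.k6p = v.Ps / v.tau_ba;
  return v;
}

inline LtccRates ltcc_rates_fast(const LtccVdep &vd, double cp, double n_open,
                                 const LtccParams &p) {
  LtccRates r;
  ltcc_coupling(n_open, cp, p, r.gamma1, r.gamma2);
  r.alpha_eff = vd.alpha * r.gamma1;
  r.beta = vd.beta;
  r.r1_eff = p.r1 * r.gamma2;
  r.r2 = p.r2;
  double q = (cp > 0.0) ? (cp / p.cpt) : 0.0;
  double q3 = q * q * q;
  double fcp = q3 / (1.0 + q3);
  r.s1 = 0.02 * fcp;
  r.k1 = 0.03 * fcp;
  r.k2 = p.k2;
  r.s1p = p.s1p;
  r.k1p = p.k1p;
  r.k2p = p.k2p;
  r.s2 = (0.02 / 0.03) * p.k2 * p.r2 / r.r1_eff;
  r.s2p = p.s1p * (p.k2p / p.k1p) * p.r2 / r.r1_eff;
  r.k3 = vd.k3;
  r.k3p = vd.k3;
  double u = cp / p.cpminus;
  double u4 = (u * u) * (u * u);
  double TCa = 114.0 / (1.0 + u4);
  double tau_ca = (vd.RV - TCa) * vd.Pr + TCa;
  r.k5 = (1.0 - vd.Ps) / tau_ca;
  r.k6 = fcp * vd.Ps / tau_ca;
  r.k5p = vd.k5p;
  r.k6p = vd.k6p;
  double ab = r.alpha_eff / r.beta;
  r.k4 = r.k3 * ab * (0.03 / p.k2) * r.k5 * tau_ca / vd.Ps;
  r.k4p = r.k3p * ab * (p.k1p / p.k2p) * (r.k5p / r.k6p);
  return r;
}

inline LtccRates ltcc_rates(double V, double cp, double n_open,
                            const LtccParams &p) {
  return ltcc_rates_fast(ltcc_vdep(V, p), cp, n_open, p);
}

// exit rate table: for each state, up to 4 (target, rate) pairs
inline int ltcc_exits(const LtccRates &r, int state, int *targets,
                      double *rates) {
  switch (state) {
  case ST_C2:
    targets[0] = ST_C1; rates[0] = r.alpha_eff;
    targets[1] = ST_I2CA; rates[1] = r.k6;
    targets[2] = ST_I2BA; rates[2] = r.k6p;
    return 3;
  case ST_C1:
    targets[0] = ST_C2; rates[0] = r.beta;
    targets[1] = ST_O; rates[1] = r.r1_eff;
    targets[2] = ST_I1CA; rates[2] = r.k1;
    targets[3] = ST_I1BA; rates[3] = r.k1p;
    return 4;
  case ST_O:
    targets[0] = ST_C1; rates[0] = r.r2;
    targets[1] = ST_I1CA; rates[1] = r.s1;
    targets[2] = ST_I1BA; rates[2] = r.s1p;
    return 3;
  case ST_I1CA:
    targets[0] = ST_O; rates[0] = r.s2;
    targets[1] = ST_C1; rates[1] = r.k2;
    targets[2] = ST_I2CA; rates[2] = r.k3;
    return 3;
  case ST_I2CA:
    targets[0] = ST_I1CA; rates[0] = r.k4;
    targets[1] = ST_C2; rates[1] = r.k5;
    return 2;
  case ST_I1BA:
    targets[0] = ST_O; rates[0] = r.s2p;
    targets[1] = ST_C1; rates[1] = r.k2p;
    targets[2] = ST_I2BA; rates[2] = r.k3p;
    return 3;
  default: // ST_I2BA
    targets[0] = ST_I1BA; rates[0] = r.k4p;
    targets[1] = ST_C2; rates[1] = r.k5p;
    return 2;
  }
}

// GHK-type single channel current; analytic limit at V = 0.
// Returns the current in the model's single-channel units (negative inward).
inline double ltcc_single_current(double V, double cp, const LtccParams &p) {
  // F in C/mmol so that z = V[mV] F / (R T) is dimensionless (V/26.54 at 35C)
  double z = V * p.Fc / (p.Rc * p.Tc);
  double num_in = 0.001 * p.gamma_i * cp;       // uM -> mM
  if (std::fabs(z) < 1e-6) {
    return 2.0 * p.PCa * p.Fc * (num_in - p.gamma_o * p.Cao);
  }
  double e2z = std::exp(2.0 * z);
  return 4.0 * p.PCa * z * p.Fc * (num_in * e2z - p.gamma_o * p.Cao) /
         (e2z - 1.0);
}

#endif
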