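#include <Rcpp.h>
#include "ltcc.h"
#include "rng.h"
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Whole-cell stochastic model: a 3-D lattice of Ca release units (CRUs).
// Each CRU holds 5 local Ca compartments (cytosolic ci, submembrane cs,
// cleft cp, network SR cnsr, junctional SR cjsr), a 4-state stochastic RyR
// cluster (100 channels) and a stochastic LTCC cluster (1..25 channels,
// 7-state Markov scheme with cooperative gating).  CRUs are coupled by
// nearest-neighbour diffusion of ci, cs and cnsr with separate longitudinal
// (x) and transverse (y, z) time constants.  The membrane potential is
// shared; sarcolemmal currents (INa, IK, IK1, IKp, background) use compact
// Luo-Rudy-style formulations, NCX / background Ca flux / sarcolemmal Ca
// pump are evaluated per CRU from the local submembrane Ca.
// ---------------------------------------------------------------------------

struct CellParams {
  LtccParams ltcc;
  // RyR 4-state ring C -> O -> I -> R -> C
  double Ku, Kcp, Kjsr, hjsr, tau_o, tau_i, tau_rr;
  double Ku_i, Kjsr_i, hjsr_i;  // luminal (depletion-driven) inactivation
  int n_ryr;
  // fluxes
  double g_rel, flux_scale;
  double vup, Kup;
  double vncx, eta, ksat, KmNa, KmCa, Nai, Nao;
  double jcab, vpmca, Kpmca;
  // relative volumes (vi = 1)
  double vs, vp, vjsr, vnsr;
  // exchange / diffusion time constants (ms)
  double tau_si, tau_p, tau_tr;
  double tau_ci_L, tau_ci_T, tau_cs_L, tau_cs_T, tau_nsr_L, tau_nsr_T;
  // buffering
  double Bcam, Kcam, Bsr, Ksr, Bcsqn, Kcsqn, BT, kon, koff;
  // membrane
  double gna, gk, gk1, gkp, gbk, ENa, alpha_conv;
  // initial values
  double ci0, cs0, cp0, cnsr0, cjsr0, V0;
};

static CellParams cell_params_from_list(const List &l) {
  CellParams p;
  p.ltcc = ltcc_params_from_list(l["ltcc"]);
  p.Ku = l["Ku"]; p.Kcp = l["Kcp"]; p.Kjsr = l["Kjsr"]; p.hjsr = l["hjsr"];
  p.tau_o = l["tau_o"]; p.tau_i = l["tau_i"]; p.tau_rr = l["tau_rr"];
  p.Ku_i = l["Ku_i"]; p.Kjsr_i = l["Kjsr_i"]; p.hjsr_i = l["hjsr_i"];
  p.n_ryr = as<int>(l["n_ryr"]);
  p.g_rel = l["g_rel"]; p.flux_scale = l["flux_scale"];
  p.vup = l["vup"]; p.Kup = l["Kup"];
  p.vncx = l["vncx"]; p.eta = l["eta"]; p.ksat = l["ksat"];
  p.KmNa = l["KmNa"]; p.KmCa = l["KmCa"]; p.Nai = l["Nai"]; p.Nao = l["Nao"];
  p.jcab = l["jcab"]; p.vpmca = l["vpmca"]; p.Kpmca = l["Kpmca"];
  p.vs = l["vs"]; p.vp = l["vp"]; p.vjsr = l["vjsr"]; p.vnsr = l["vnsr"];
  p.tau_si = l["tau_si"]; p.tau_p = l["tau_p"]; p.tau_tr = l["tau_tr"];
  p.tau_ci_L = l["tau_ci_L"]; p.tau_ci_T = l["tau_ci_T"];
  p.tau_cs_L = l["tau_cs_L"]; p.tau_cs_T = l["tau_cs_T"];
  p.tau_nsr_L = l["tau_nsr_L"]; p.tau_nsr_T = l["tau_nsr_T"];
  p.Bcam = l["Bcam"]; p.Kcam = l["Kcam"]; p.Bsr = l["Bsr"]; p.Ksr = l["Ksr"];
  p.Bcsqn = l["Bcsqn"]; p.Kcsqn = l["Kcsqn"];
  p.BT = l["BT"]; p.kon = l["kon"]; p.koff = l["koff"];
  p.gna = l["gna"]; p.gk = l["gk"]; p.gk1 = l["gk1"]; p.gkp = l["gkp"];
  p.gbk = l["gbk"]; p.ENa = l["ENa"]; p.alpha_conv = l["alpha_conv"];
  p.ci0 = l["ci0"]; p.cs0 = l["cs0"]; p.cp0 = l["cp0"];
  p.cnsr0 = l["cnsr0"]; p.cjsr0 = l["cjsr0"]; p.V0 = l["V0"];
  return p;
}

static inline double beta_cyt(double c, const CellParams &p) {
  double a = p.Bcam * p.Kcam / ((p.Kcam + c) * (p.Kcam + c));
  double b = p.Bsr * p.Ksr / ((p.Ksr + c) * (p.Ksr + c));
  return 1.0 / (1.0 + a + b);
}
static inline double beta_jsr(double c, const CellParams &p) {
  double a = p.Bcsqn * p.Kcsqn / ((p.Kcsqn + c) * (p.Kcsqn + c));
  return 1.0 / (1.0 + a);
}
// closed-state inactivation driven by JSR depletion (calsequestrin-type
// luminal sensing): significant only while the local SR is depleted, the
// source of beat-to-beat release refractoriness.
static inline double ryr_ci_rate(double cjsr, const CellParams &p) {
  if (p.Ku_i <= 0.0) return 0.0;
  return p.Ku_i / (1.0 + std::pow(std::max(cjsr, 0.0) / p.Kjsr_i, p.hjsr_i));
}
static inline double ryr_open_rate(double cp, double cjsr,
                                   const CellParams &p) {
  if (cp <= 0.0) return 0.0;
  double c2 = cp * cp;
  double phi = 1.0 / (1.0 + std::pow(p.Kjsr / std::max(cjsr, 1e-12), p.hjsr));
  return p.Ku * phi * c2 / (c2 + p.Kcp * p.Kcp);
}

// --- Luo-Rudy style sarcolemmal gate kinetics ------------------------------
static inline void gate_m(double V, double &a, double &b) {
  double d = V + 47.13;
  a = (std::fabs(d) < 1e-6) ? 3.2 : 0.32 * d / (1.0 - std::exp(-0.1 * d));
  b = 0.08 * std::exp(-V / 11.0);
}
static inline void gate_h(double V, double &a, double &b) {
  if (V < -40.0) {
    a = 0.135 * std::exp(-(80.0 + V) / 6.8);
    b = 3.56 * std::exp(0.079 * V) + 3.1e5 * std::exp(0.35 * V);
  } else {
    a = 0.0;
    b = 1.0 / (0.13 * (1.0 + std::exp(-(V + 10.66) / 11.1)));
  }
}
static inline void gate_j(double V, double &a, double &b) {
  if (V < -40.0) {
    a = (-1.2714e5 * std::exp(0.2444 * V) - 3.474e-5 * std::exp(-0.04391 * V)) *
        (V + 37.78) / (1.0 + std::exp(0.311 * (V + 79.23)));
    b = 0.1212 * std::exp(-0.01052 * V) /
        (1.0 + std::exp(-0.1378 * (V + 40.14)));
  } else {
    a = 0.0;
    b = 0.3 * std::exp(-2.535e-7 * V) / (1.0 + std::exp(-0.1 * (V + 32.0)));
  }
}
static inline void gate_x(double V, double &a, double &b) {
  a = 0.0005 * std::exp(0.083 * (V + 50.0)) /
      (1.0 + std::exp(0.057 * (V + 50.0)));
  b = 0.0013 * std::exp(-0.06 * (V + 20.0)) /
      (1.0 + std::exp(-0.04 * (V + 20.0)));
}
static inline double xi_k(double V) {
  if (V > -100.0) {
    double d = V + 77.0;
    if (std::fabs(d) < 1e-6) return 2.837 * 0.04 / std::exp(0.04 * (V + 35.0));
    return 2.837 * (std::exp(0.04 * d) - 1.0) / (d * std::exp(0.04 * (V + 35.0)));
  }
  return 1.0;
}
static inline double k1_inf(double V) {
  double E = -87.2;
  double a = 1.02 / (1.0 + std::exp(0.2385 * (V - E - 59.215)));
  double b = (0.49124 * std::exp(0.08032 * (V - E + 5.476)) +
              std::exp(0.06175 * (V - E - 594.31))) /
             (1.0 + std::exp(-0.5143 * (V - E + 4.753)));
  return a / (a + b);
}

struct CellState {
  int nc, nx, ny, nz;
  std::vector<double> ci, cs, cp, cnsr, cjsr, tni, tns;
  std::vector<int> ryrC, ryrO, ryrI, ryrR;
  std::vector<int> cluster_size, cluster_off, n_open;
  std::vector<signed char> chan;
  double V, gm, gh, gj, gx;
};

static void init_state(CellState &S, int nx, int ny, int nz,
                       const IntegerVector &sizes, const CellParams &p) {
  S.nx = nx; S.ny = ny; S.nz = nz; S.nc = nx * ny * nz;
  int nc = S.nc;
  S.ci.assign(nc, p.ci0); S.cs.assign(nc, p.cs0); S.cp.assign(nc, p.cp0);
  S.cnsr.assign(nc, p.cnsr0); S.cjsr.assign(nc, p.cjsr0);
  double tn0 = p.BT * p.kon * p.ci0 / (p.kon * p.ci0 + p.koff);
  S.tni.assign(nc, tn0); S.tns.assign(nc, tn0);
  S.ryrC.assign(nc, p.n_ryr); S.ryrO.assign(nc, 0);
  S.ryrI.assign(nc, 0); S.ryrR.assign(nc, 0);
  S.cluster_size.assign(sizes.begin(), sizes.end());
  S.cluster_off.assign(nc, 0);
  int tot = 0;
  for (int i = 0; i < nc; ++i) { S.cluster_off[i] = tot; tot += S.cluster_size[i]; }
  S.chan.assign(tot, (signed char)ST_C2);
  S.n_open.assign(nc, 0);
  S.V = p.V0;
  double a, b;
  gate_m(S.V, a, b); S.gm = a / (a + b);
  gate_h(S.V, a, b); S.gh = a / (a + b);
  gate_j(S.V, a, b); S.gj = a / (a + b);
  gate_x(S.V, a, b); S.gx = a / (a + b);
}

static List state_to_list(const CellState &S) {
  return List::create(
      _["ci"] = NumericVector(S.ci.begin(), S.ci.end()),
      _["cs"] = NumericVector(S.cs.begin(), S.cs.end()),
      _["cp"] = NumericVector(S.cp.begin(), S.cp.end()),
      _["cnsr"] = NumericVector(S.cnsr.begin(), S.cnsr.end()),
      _["cjsr"] = NumericVector(S.cjsr.begin(), S.cjsr.end()),
      _["tni"] = NumericVector(S.tni.begin(), S.tni.end()),
      _["tns"] = NumericVector(S.tns.begin(), S.tns.end()),
      _["ryrC"] = IntegerVector(S.ryrC.begin(), S.ryrC.end()),
      _["ryrO"] = IntegerVector(S.ryrO.begin(), S.ryrO.end()),
      _["ryrI"] = IntegerVector(S.ryrI.begin(), S.ryrI.end()),
      _["ryrR"] = IntegerVector(S.ryrR.begin(), S.ryrR.end()),
      _["cluster_size"] =
          IntegerVector(S.cluster_size.begin(), S.cluster_size.end()),
      _["chan"] = IntegerVector(S.chan.begin(), S.chan.end()),
      _["V"] = S.V, _["gm"] = S.gm, _["gh"] = S.gh, _["gj"] = S.gj,
      _["gx"] = S.gx);
}

static void state_from_list(CellState &S, const List &l, int nx, int ny,
                            int nz) {
  S.nx = nx; S.ny = ny; S.nz = nz; S.nc = nx * ny * nz;
  NumericVector ci = l["ci"], cs = l["cs"], cp = l["cp"], cnsr = l["cnsr"],
                cjsr = l["cjsr"], tni = l["tni"], tns = l["tns"];
  IntegerVector rC = l["ryrC"], rO = l["ryrO"], rI = l["ryrI"], rR = l["ryrR"],
                csz = l["cluster_size"], chan = l["chan"];
  S.ci.assign(ci.begin(), ci.end()); S.cs.assign(cs.begin(), cs.end());
  S.cp.assign(cp.begin(), cp.end()); S.cnsr.assign(cnsr.begin(), cnsr.end());
  S.cjsr.assign(cjsr.begin(), cjsr.end());
  S.tni.assign(tni.begin(), tni.end()); S.tns.assign(tns.begin(), tns.end());
  S.ryrC.assign(rC.begin(), rC.end()); S.ryrO.assign(rO.begin(), rO.end());
  S.ryrI.assign(rI.begin(), rI.end()); S.ryrR.assign(rR.begin(), rR.end());
  S.cluster_size.assign(csz.begin(), csz.end());
  S.cluster_off.assign(S.nc, 0);
  int tot = 0;
  for (int i = 0; i < S.nc; ++i) { S.cluster_off[i] = tot; tot += S.cluster_size[i]; }
  S.chan.resize(tot);
  for (int i = 0; i < tot; ++i) S.chan[i] = (signed char)chan[i];
  S.n_open.assign(S.nc, 0);
  for (int i = 0; i < S.nc; ++i)
    for (int k = 0; k < S.cluster_size[i]; ++k)
      if (S.chan[S.cluster_off[i] + k] == ST_O) S.n_open[i]++;
  S.V = l["V"]; S.gm = l["gm"]; S.gh = l["gh"]; S.gj = l["gj"]; S.gx = l["gx"];
}

// volume-weighted total Ca (free + buffered, cytosol-volume units of vi = 1)
static double total_calcium(const CellState &S, const CellParams &p) {
  double tot = 0.0;
  for (int i = 0; i < S.nc; ++i) {
    double ci = S.ci[i], cs = S.cs[i];
    double bi = p.Bcam * ci / (p.Kcam + ci) + p.Bsr * ci / (p.Ksr + ci);
    double bs = p.Bcam * cs / (p.Kcam + cs) + p.Bsr * cs / (p.Ksr + cs);
    double bj = p.Bcsqn * S.cjsr[i] / (p.Kcsqn + S.cjsr[i]);
    tot += (ci + bi + S.tni[i]) + p.vs * (cs + bs + S.tns[i]) +
           p.vp * S.cp[i] + p.vnsr * S.cnsr[i] + p.vjsr * (S.cjsr[i] + bj);
  }
  return tot / S.nc;
}

// one explicit update of all local concentrations (channel states frozen);
// returns whole-cell fluxes for the current step via the out parameters.
static bool conc_substep(CellState &S, const CellParams &p, double dt,
                         double ncxA, double ncxB,
                         double &jcal_cyt, double &jncx_cyt,
                         double &jcab_cyt, double &jpmca_cyt) {
  int nc = S.nc, nx = S.nx, ny = S.ny, nz = S.nz;
  static thread_local std::vector<double> dci, dcs, dcp, dcn, dcj, dti, dts;
  dci.assign(nc, 0.0); dcs.assign(nc, 0.0); dcp.assign(nc, 0.0);
  dcn.assign(nc, 0.0); dcj.assign(nc, 0.0); dti.assign(nc, 0.0);
  dts.assign(nc, 0.0);
  jcal_cyt = jncx_cyt = jcab_cyt = jpmca_cyt = 0.0;

  for (int iz = 0; iz < nz; ++iz)
    for (int iy = 0; iy < ny; ++iy)
      for (int ix = 0; ix < nx; ++ix) {
        int i = ix + nx * (iy + ny * iz);
        double ci = S.ci[i], cs = S.cs[i], cp = S.cp[i];
        double cn = S.cnsr[i], cj = S.cjsr[i];

        // nearest-neighbour diffusion (no-flux boundaries)
        double Ici = 0.0, Ics = 0.0, Icn = 0.0;
        if (ix > 0) { int n = i - 1;
          Ici += (S.ci[n] - ci) / p.tau_ci_L;
          Ics += (S.cs[n] - cs) / p.tau_cs_L;
          Icn += (S.cnsr[n] - cn) / p.tau_nsr_L; }
        if (ix < nx - 1) { int n = i + 1;
          Ici += (S.ci[n] - ci) / p.tau_ci_L;
          Ics += (S.cs[n] - cs) / p.tau_cs_L;
          Icn += (S.cnsr[n] - cn) / p.tau_nsr_L; }
        if (iy > 0) { int n = i - nx;
          Ici += (S.ci[n] - ci) / p.tau_ci_T;
          Ics += (S.cs[n] - cs) / p.tau_cs_T;
          Icn += (S.cnsr[n] - cn) / p.tau_nsr_T; }
        if (iy < ny - 1) { int n = i + nx;
          Ici += (S.ci[n] - ci) / p.tau_ci_T;
          Ics += (S.cs[n] - cs) / p.tau_cs_T;
          Icn += (S.cnsr[n] - cn) / p.tau_nsr_T; }
        if (iz > 0) { int n = i - nx * ny;
          Ici += (S.ci[n] - ci) / p.tau_ci_T;
          Ics += (S.cs[n] - cs) / p.tau_cs_T;
          Icn += (S.cnsr[n] - cn) / p.tau_nsr_T; }
        if (iz < nz - 1) { int n = i + nx * ny;
          Ici += (S.ci[n] - ci) / p.tau_ci_T;
          Ics += (S.cs[n] - cs) / p.tau_cs_T;
          Icn += (S.cnsr[n] - cn) / p.tau_nsr_T; }

        double Idsi = (cs - ci) / p.tau_si;
        double Idps = (cp - cs) / p.tau_p;
        double Itr = (cn - cj) / p.tau_tr;
        double Iup = p.vup * ci * ci / (ci * ci + p.Kup * p.Kup);
        double Ir = p.g_rel * ((double)S.ryrO[i] / p.n_ryr) * (cj - cp);
        double ical = ltcc_single_current(S.V, cp, p.ltcc);
        double Jcal = -p.flux_scale * ical * S.n_open[i];
        double Jncx = ncxA - ncxB * cs;
        double Jpmca = p.vpmca * cs * cs / (cs * cs + p.Kpmca * p.Kpmca);
        double ITCi = p.kon * ci * (p.BT - S.tni[i]) - p.koff * S.tni[i];
        double ITCs = p.kon * cs * (p.BT - S.tns[i]) - p.koff * S.tns[i];

        dci[i] = beta_cyt(ci, p) * (Idsi * p.vs - Iup - ITCi + Ici);
        dcs[i] = beta_cyt(cs, p) * (Idps * (p.vp / p.vs) + Jncx - Idsi -
                                    ITCs + Ics + p.jcab - Jpmca);
        dcp[i] = Ir + Jcal - Idps;
        dcn[i] = (Iup - Itr * p.vjsr) / p.vnsr + Icn;
        dcj[i] = beta_jsr(cj, p) * (Itr - Ir * (p.vp / p.vjsr));
        dti[i] = ITCi;
        dts[i] = ITCs;

        jcal_cyt += Jcal * p.vp;
        jncx_cyt += Jncx * p.vs;
        jcab_cyt += p.jcab * p.vs;
        jpmca_cyt += Jpmca * p.vs;
      }

  bool ok = true;
  for (int i = 0; i < nc; ++i) {
    S.ci[i] += dt * dci[i]; S.cs[i] += dt * dcs[i]; S.cp[i] += dt * dcp[i];
    S.cnsr[i] += dt * dcn[i]; S.cjsr[i] += dt * dcj[i];
    S.tni[i] += dt * dti[i]; S.tns[i] += dt * dts[i];
    if (S.ci[i] < 0.0 || S.cs[i] < 0.0 || S.cp[i] < 0.0 || S.cnsr[i] < 0.0 ||
        S.cjsr[i] < 0.0)
      ok = false;
  }
  jcal_cyt /= nc; jncx_cyt /= nc; jcab_cyt /= nc; jpmca_cyt /= nc;
  return ok;
}

// [[Rcpp::export(name = ".build_cluster_sizes_cpp")]]
IntegerVector build_cluster_sizes_cpp(int n, double mean, double sd,
                                      int minc, int maxc, int seed) {
  Xoshiro rng;
  rng.seed((uint64_t)seed, 0xC1u);
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    // Box-Muller
    double u1 = rng.unif(), u2 = rng.unif();
    if (u1 <= 0.0) u1 = 0x1.0p-53;
    double g = std::sqrt(-2.0 * std::log(u1)) * std::cos(2.0 * M_PI * u2);
    int k = (int)std::lround(mean + sd * g);
    if (k < minc) k = minc;
    if (k > maxc) k = maxc;
    out[i] = k;
  }
  return out;
}

// [[Rcpp::export(name = ".run_lattice_cpp")]]
List run_lattice_cpp(int nx, int ny, int nz, IntegerVector cluster_sizes,
                     List params, List protocol, SEXP init, int seed,
                     double dt, int stride) {
  CellParams p = cell_params_from_list(params);
  int nc = nx * ny * nz;

  CellState S;
  if (Rf_isNull(init)) {
    if (cluster_sizes.size() != nc)
      stop("cluster_sizes must have one entry per CRU");
    init_state(S, nx, ny, nz, cluster_sizes, p);
  } else {
    state_from_list(S, List(init), nx, ny, nz);
  }

  std::string kind = as<std::string>(protocol["kind"]);
  double duration, pcl = 0, stim_amp = 0, stim_dur = 0;
  double v_hold = 0, v_test = 0, t_hold = 0, t_test = 0;
  NumericVector waveform;
  double wave_dt = 1.0;
  bool freeze = protocol.containsElementNamed("freeze_channels")
                    ? as<bool>(protocol["freeze_channels"])
                    : false;
  if (kind == "vclamp") {
    v_hold = protocol["v_hold"]; v_test = protocol["v_test"];
    t_hold = protocol["t_hold"]; t_test = protocol["t_test"];
    duration = t_hold + t_test;
    S.V = v_hold;
  } else if (kind == "paced") {
    pcl = protocol["pcl"];
    stim_amp = protocol["stim_amp"]; stim_dur = protocol["stim_dur"];
    duration = pcl * as<double>(protocol["n_beats"]);
  } else if (kind == "apclamp") {
    pcl = protocol["pcl"];
    waveform = protocol["waveform"];
    wave_dt = protocol["wave_dt"];
    duration = pcl * as<double>(protocol["n_beats"]);
  } else if (kind == "free") {
    duration = protocol["duration"];
  } else {
    stop("unknown protocol kind '%s'", kind.c_str());
  }
  int n_steps = (int)std::lround(duration / dt);

  std::vector<Xoshiro> rng(nc);
  for (int i = 0; i < nc; ++i) rng[i].seed((uint64_t)seed, (uint64_t)i + 1);

  int n_rec = n_steps / stride + 1;
  NumericVector rt(n_rec), rV(n_rec), rical(n_rec), rincx(n_rec),
      rci(n_rec), rcs(n_rec), rcp(n_rec), rcn(n_rec), rcj(n_rec),
      rtot(n_rec);
  IntegerVector rnl(n_rec), rno(n_rec);
  int irec = 0;
  long clamped = 0;

  // RyR closed-loop transition probabilities that do not depend on Ca
  double pOI = -std::expm1(-dt / p.tau_o);
  double pIR = -std::expm1(-dt / p.tau_i);
  double pRC = -std::expm1(-dt / p.tau_rr);

  double ICaL = 0.0, INaCa = 0.0;

  for (int t = 0; t < n_steps; ++t) {
    double tm = t * dt;

    // commanded membrane potential
    if (kind == "vclamp") {
      S.V = (tm < t_hold) ? v_hold : v_test;
    } else if (kind == "apclamp") {
      double tb = std::fmod(tm, pcl);
      double x = tb / wave_dt;
      int i0 = (int)x;
      double fr = x - i0;
      int i1 = std::min(i0 + 1, (int)waveform.size() - 1);
      i0 = std::min(i0, (int)waveform.size() - 1);
      S.V = waveform[i0] * (1.0 - fr) + waveform[i1] * fr;
    }

    // per-step voltage-only precomputation
    LtccVdep vd = ltcc_vdep(S.V, p.ltcc);
    double z = S.V * p.ltcc.Fc / (p.ltcc.Rc * p.ltcc.Tc);
    double e1 = std::exp(p.eta * z), e2 = std::exp((p.eta - 1.0) * z);
    double Na3 = p.Nai * p.Nai * p.Nai, Nao3 = p.Nao * p.Nao * p.Nao;
    double denom = (p.KmNa * p.KmNa * p.KmNa + Nao3) * (p.KmCa + p.ltcc.Cao) *
                   (1.0 + p.ksat * e2);
    double ncxA = p.vncx * e1 * Na3 * p.ltcc.Cao / denom;
    double ncxB = p.vncx * e2 * Nao3 * 0.001 / denom;

    // concentrations (retry with substeps on negativity)
    static thread_local std::vector<double> sci, scs, scp, scn, scj, sti, sts;
    sci = S.ci; scs = S.cs; scp = S.cp; scn = S.cnsr; scj = S.cjsr;
    sti = S.tni; sts = S.tns;
    double jcal, jncx, jcab, jpm;
    bool ok = conc_substep(S, p, dt, ncxA, ncxB, jcal, jncx, jcab, jpm);
    if (!ok) {
      S.ci = sci; S.cs = scs; S.cp = scp; S.cnsr = scn; S.cjsr = scj;
      S.tni = sti; S.tns = sts;
      bool ok2 = true;
      for (int ss = 0; ss < 4; ++ss)
        ok2 = conc_substep(S, p, dt / 4.0, ncxA, ncxB, jcal, jncx, jcab, jpm) &&
              ok2;
      if (!ok2) {
        for (int i = 0; i < nc; ++i) {
          if (S.ci[i] < 0) { S.ci[i] = 0; ++clamped; }
          if (S.cs[i] < 0) { S.cs[i] = 0; ++clamped; }
          if (S.cp[i] < 0) { S.cp[i] = 0; ++clamped; }
          if (S.cnsr[i] < 0) { S.cnsr[i] = 0; ++clamped; }
          if (S.cjsr[i] < 0) { S.cjsr[i] = 0; ++clamped; }
        }
      }
    }

    ICaL = -2.0 * p.alpha_conv * jcal;
    INaCa = p.alpha_conv * jncx;
    double ICab = -2.0 * p.alpha_conv * jcab;
    double IpCa = 2.0 * p.alpha_conv * jpm;

    // stochastic channel updates (states at start of step; rates use the
    // pre-update concentrations which conc_substep has already advanced --
    // order matches the explicit operator split, channel rates see the
    // freshly updated local Ca)
    if (!freeze) {
      for (int i = 0; i < nc; ++i) {
        Xoshiro &R = rng[i];
        double cp = S.cp[i];
        // RyR: C -> O (Ca and JSR dependent), O -> I -> R -> C
        double ko = ryr_open_rate(cp, S.cjsr[i], p);
        double pCO = -std::expm1(-ko * dt);
        double kci = ryr_ci_rate(S.cjsr[i], p);
        int nCO = R.binom(S.ryrC[i], pCO);
        int nCI = (kci > 0.0)
                      ? R.binom(S.ryrC[i] - nCO, -std::expm1(-kci * dt))
                      : 0;
        int nOI = R.binom(S.ryrO[i], pOI);
        int nIR = R.binom(S.ryrI[i], pIR);
        int nRC = R.binom(S.ryrR[i], pRC);
        S.ryrC[i] += nRC - nCO - nCI;
        S.ryrO[i] += nCO - nOI;
        S.ryrI[i] += nOI + nCI - nIR;
        S.ryrR[i] += nIR - nRC;

        // LTCC cluster.  Fast path: per-channel Bernoulli transitions when
        // every per-state exit probability is below 0.09.  Some rates
        // (notably the I2Ca -> C2 recovery, whose time constant T_Ca
        // collapses at high cleft Ca) can exceed that bound; those steps
        // fall back to an exact embedded-chain (Gillespie) simulation of
        // each channel over [0, dt) with the rates frozen at the step
        // start, which resolves arbitrarily fast transitions at O(#jumps)
        // cost.
        int ncl = S.cluster_size[i];
        int off = S.cluster_off[i];
        double cum[7][4], tot[7];
        int tg[7][4], nex[7];
        int targets[4]; double rates[4];
        LtccRates lr = ltcc_rates_fast(vd, cp, (double)S.n_open[i], p.ltcc);
        double maxacc = 0.0;
        for (int s = 0; s < 7; ++s) {
          int ne = ltcc_exits(lr, s, targets, rates);
          nex[s] = ne;
          double acc = 0.0;
          for (int e = 0; e < ne; ++e) {
            acc += rates[e];
            cum[s][e] = acc * dt; tg[s][e] = targets[e];
          }
          tot[s] = acc;
          if (acc * dt > maxacc) maxacc = acc * dt;
        }
        int nop = S.n_open[i];
        if (maxacc < 0.09) {
          for (int k = 0; k < ncl; ++k) {
            int s = S.chan[off + k];
            double u = R.unif();
            if (u < cum[s][nex[s] - 1]) {
              int e = 0;
              while (u >= cum[s][e]) ++e;
              int ns2 = tg[s][e];
              if (s == ST_O) --nop;
              if (ns2 == ST_O) ++nop;
              S.chan[off + k] = (signed char)ns2;
            }
          }
        } else {
          for (int k = 0; k < ncl; ++k) {
            int s = S.chan[off + k];
            double trem = dt;
            for (int guard = 0; guard < 200; ++guard) {
              double lam = tot[s];
              if (lam <= 0.0) break;
              double u = R.unif();
              if (u <= 0.0) u = 0x1.0p-53;
              double tau = -std::log(u) / lam;
              if (tau >= trem) break;
              trem -= tau;
              double v = R.unif() * lam * dt;  // cum[] is rate*dt scaled
              int e = 0;
              while (e < nex[s] - 1 && v >= cum[s][e]) ++e;
              int ns2 = tg[s][e];
              if (s == ST_O) --nop;
              if (ns2 == ST_O) ++nop;
              s = ns2;
            }
            S.chan[off + k] = (signed char)s;
          }
        }
        S.n_open[i] = nop;
      }
    }

    // membrane potential
    if (kind == "paced" || kind == "free") {
      double V = S.V;
      double INa = p.gna * S.gm * S.gm * S.gm * S.gh * S.gj * (V - p.ENa);
      double IK = p.gk * S.gx * xi_k(V) * (V + 77.0);
      double IK1 = p.gk1 * k1_inf(V) * (V + 87.2);
      double IKp = p.gkp * (V + 87.2) / (1.0 + std::exp((7.488 - V) / 5.98));
      double Ib = p.gbk * (V + 59.87);
      double Istim = 0.0;
      if (kind == "paced") {
        double tb = std::fmod(tm, pcl);
        if (tb < stim_dur) Istim = stim_amp;
      }
      double Iion = INa + IK + IK1 + IKp + Ib + ICaL + INaCa + ICab + IpCa;
      S.V = V - dt * (Iion + Istim);
      if (!std::isfinite(S.V) || S.V < -150.0 || S.V > 150.0)
        stop("membrane potential diverged at t = %.2f ms (V = %.1f)", tm, S.V);
      double a, b;
      gate_m(V, a, b); double inf = a / (a + b);
      S.gm = inf + (S.gm - inf) * std::exp(-dt * (a + b));
      gate_h(V, a, b); inf = a / (a + b);
      S.gh = inf + (S.gh - inf) * std::exp(-dt * (a + b));
      gate_j(V, a, b); inf = a / (a + b);
      S.gj = inf + (S.gj - inf) * std::exp(-dt * (a + b));
      gate_x(V, a, b); inf = a / (a + b);
      S.gx = inf + (S.gx - inf) * std::exp(-dt * (a + b));
    }

    if (t % stride == 0) {
      double mci = 0, mcs = 0, mcp = 0, mcn = 0, mcj = 0;
      int nl = 0, no = 0;
      for (int i = 0; i < nc; ++i) {
        mci += S.ci[i]; mcs += S.cs[i]; mcp += S.cp[i];
        mcn += S.cnsr[i]; mcj += S.cjsr[i];
        nl += S.n_open[i]; no += S.ryrO[i];
      }
      rt[irec] = tm; rV[irec] = S.V; rical[irec] = ICaL; rincx[irec] = INaCa;
      rci[irec] = mci / nc; rcs[irec] = mcs / nc; rcp[irec] = mcp / nc;
      rcn[irec] = mcn / nc; rcj[irec] = mcj / nc;
      rnl[irec] = nl; rno[irec] = no;
      rtot[irec] = total_calcium(S, p);
      ++irec;
    }
  }

  DataFrame trace = DataFrame::create(
      _["time_ms"] = rt[Range(0, irec - 1)], _["v_mV"] = rV[Range(0, irec - 1)],
      _["ical_AF"] = rical[Range(0, irec - 1)],
      _["incx_AF"] = rincx[Range(0, irec - 1)],
      _["ci_uM"] = rci[Range(0, irec - 1)], _["cs_uM"] = rcs[Range(0, irec - 1)],
      _["cp_uM"] = rcp[Range(0, irec - 1)],
      _["cnsr_uM"] = rcn[Range(0, irec - 1)],
      _["cjsr_uM"] = rcj[Range(0, irec - 1)],
      _["n_open_ltcc"] = rnl[Range(0, irec - 1)],
      _["n_open_ryr"] = rno[Range(0, irec - 1)],
      _["total_ca_uM"] = rtot[Range(0, irec - 1)]);
  return List::create(_["trace"] = trace, _["final"] = state_to_list(S),
                      _["clamped"] = (double)clamped);
}

// Isolated-CRU spark trials: the cleft Ca is clamped to a rectangular pulse,
// the junctional SR is held at its initial load, and the peak number of
// simultaneously open RyRs per trial is recorded.
// [[Rcpp::export(name = ".spark_trials_cpp")]]
List spark_trials_cpp(List params, double cp_pulse, double pulse_dur,
                      double duration, double dt, int n_trials, int seed,
                      double cp_base) {
  CellParams p = cell_params_from_list(params);
  int n_steps = (int)std::lround(duration / dt);
  IntegerVector peaks(n_trials);
  IntegerVector example(n_steps);
  double pOI = -std::expm1(-dt / p.tau_o);
  double pIR = -std::expm1(-dt / p.tau_i);
  double pRC = -std::expm1(-dt / p.tau_rr);
  for (int trial = 0; trial < n_trials; ++trial) {
    Xoshiro R;
    R.seed((uint64_t)seed, (uint64_t)trial + 1);
    int nC = p.n_ryr, nO = 0, nI = 0, nR = 0, peak = 0;
    for (int t = 0; t < n_steps; ++t) {
      double tm = t * dt;
      double cp = (tm < pulse_dur) ? cp_pulse : cp_base;
      double ko = ryr_open_rate(cp, p.cjsr0, p);
      double pCO = -std::expm1(-ko * dt);
      double kci = ryr_ci_rate(p.cjsr0, p);
      int nCO = R.binom(nC, pCO);
      int nCI = (kci > 0.0) ? R.binom(nC - nCO, -std::expm1(-kci * dt)) : 0;
      int nOI = R.binom(nO, pOI);
      int nIR = R.binom(nI, pIR);
      int nRC = R.binom(nR, pRC);
      nC += nRC - nCO - nCI; nO += nCO - nOI; nI += nOI + nCI - nIR;
      nR += nIR - nRC;
      if (nO > peak) peak = nO;
      if (trial == 0) example[t] = nO;
    }
    peaks[trial] = peak;
  }
  return List::create(_["peaks"] = peaks, _["example_n_open"] = example);
}

// Right-hand side of the five local Ca ODEs of one CRU (fluxes broken out),
// for tests and documentation.  neighbours: matrix with one row per
// neighbour, columns (ci, cs, cnsr, longitudinal 0/1).
// [[Rcpp::export(name = ".cru_rhs_cpp")]]
List cru_rhs_cpp(NumericVector state, SEXP neighbours, double V,
                 int n_open_ltcc, int n_open_ryr, List params) {
  CellParams p = cell_params_from_list(params);
  double ci = state["ci"], cs = state["cs"], cp = state["cp"],
         cn = state["cnsr"], cj = state["cjsr"], tni = state["tni"],
         tns = state["tns"];
  double Ici = 0, Ics = 0, Icn = 0;
  if (!Rf_isNull(neighbours)) {
    NumericMatrix nb(neighbours);
    for (int r = 0; r < nb.nrow(); ++r) {
      bool lon = nb(r, 3) > 0.5;
      Ici += (nb(r, 0) - ci) / (lon ? p.tau_ci_L : p.tau_ci_T);
      Ics += (nb(r, 1) - cs) / (lon ? p.tau_cs_L : p.tau_cs_T);
      Icn += (nb(r, 2) - cn) / (lon ? p.tau_nsr_L : p.tau_nsr_T);
    }
  }
  double z = V * p.ltcc.Fc / (p.ltcc.Rc * p.ltcc.Tc);
  double e1 = std::exp(p.eta * z), e2 = std::exp((p.eta - 1.0) * z);
  double Na3 = p.Nai * p.Nai * p.Nai, Nao3 = p.Nao * p.Nao * p.Nao;
  double denom = (p.KmNa * p.KmNa * p.KmNa + Nao3) * (p.KmCa + p.ltcc.Cao) *
                 (1.0 + p.ksat * e2);
  double Jncx = p.vncx * (e1 * Na3 * p.ltcc.Cao - e2 * Nao3 * 0.001 * cs) / denom;
  double Idsi = (cs - ci) / p.tau_si;
  double Idps = (cp - cs) / p.tau_p;
  double Itr = (cn - cj) / p.tau_tr;
  double Iup = p.vup * ci * ci / (ci * ci + p.Kup * p.Kup);
  double Ir = p.g_rel * ((double)n_open_ryr / p.n_ryr) * (cj - cp);
  double Jcal = -p.flux_scale * ltcc_single_current(V, cp, p.ltcc) *
                n_open_ltcc;
  double Jpmca = p.vpmca * cs * cs / (cs * cs + p.Kpmca * p.Kpmca);
  double ITCi = p.kon * ci * (p.BT - tni) - p.koff * tni;
  double ITCs = p.kon * cs * (p.BT - tns) - p.koff * tns;

  NumericVector d = NumericVector::create(
      _["ci"] = beta_cyt(ci, p) * (Idsi * p.vs - Iup - ITCi + Ici),
      _["cs"] = beta_cyt(cs, p) * (Idps * (p.vp / p.vs) + Jncx - Idsi - ITCs +
                                   Ics + p.jcab - Jpmca),
      _["cp"] = Ir + Jcal - Idps,
      _["cnsr"] = (Iup - Itr * p.vjsr) / p.vnsr + Icn,
      _["cjsr"] = beta_jsr(cj, p) * (Itr - Ir * (p.vp / p.vjsr)),
      _["tni"] = ITCi, _["tns"] = ITCs);
  List fluxes = List::create(
      _["I_dsi"] = Idsi, _["I_dps"] = Idps, _["I_tr"] = Itr, _["I_up"] = Iup,
      _["I_r"] = Ir, _["J_CaL"] = Jcal, _["J_NCX"] = Jncx,
      _["J_pmca"] = Jpmca, _["I_TCi"] = ITCi, _["I_TCs"] = ITCs,
      _["I_ci"] = Ici, _["I_cs"] = Ics, _["I_cNSR"] = Icn,
      _["beta_i"] = beta_cyt(ci, p), _["beta_s"] = beta_cyt(cs, p),
      _["beta_p"] = 1.0, _["beta_JSR"] = beta_jsr(cj, p));
  return List::create(_["deriv"] = d, _["fluxes"] = fluxes);
}

// [[Rcpp::export(name = ".ryr_open_rate_cpp")]]
double ryr_open_rate_cpp(double cp, double cjsr, List params) {
  CellParams p = cell_params_from_list(params);
  return ryr_open_rate(cp, cjsr, p);
}

// [[Rcpp::export(name = ".total_calcium_cpp")]]
double total_calcium_cpp(List state, List params, int nx, int ny, int nz) {
  CellParams p = cell_params_from_list(params);
  CellState S;
  state_from_list(S, state, nx, ny, nz);
  return total_calcium(S, p);
}
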