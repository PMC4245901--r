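// Network integration core.
//
// Hybrid scheme: the five continuous states per neuron (v, n, h, r, Ca)
// are advanced with an embedded Runge-Kutta-Fehlberg 4(5) method with
// per-neuron adaptive step size, while all discrete interactions
// (delayed spike delivery, STDP updates, Poisson noise arrivals,
// stimulation phase changes) live on a fixed event grid (0.1 ms).
// Alpha-function synaptic kernels are class-aggregated per neuron and
// advanced analytically (two auxiliary linear states z, a per kernel
// slot; a spike of weight w sets z += w, and the summed postsynaptic
// kernel equals a(t)/tau exactly). Within one event interval neurons
// are mutually decoupled, so each neuron integrates independently.
//
// Gating sigmoids/time constants are evaluated through fine lookup
// tables built at R level from the definitional gating functions.

#include <Rcpp.h>
#include <vector>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

namespace {

struct Lut {
  double x0, dx_inv;
  int n;
  std::vector<double> y;
  inline double eval(double x) const {
    double u = (x - x0) * dx_inv;
    if (u <= 0) return y.front();
    if (u >= n - 1) return y.back();
    int i = (int)u;
    double f = u - i;
    return y[i] + f * (y[i + 1] - y[i]);
  }
};

static Lut make_lut(NumericVector vals, double x0, double dx) {
  Lut L;
  L.x0 = x0;
  L.dx_inv = 1.0 / dx;
  L.n = vals.size();
  L.y.assign(vals.begin(), vals.end());
  return L;
}

// gating tables per cell kind
struct KindTables {
  Lut minf, hinf, ninf, rinf, ainf, sinf, tauh, taun, taur;
  Lut binf;              // STN only (function of r)
  bool has_b = false;
  double phi_h, phi_n, phi_r, k1, k_Ca, eps, c_m, I_app;
};

// per-neuron biophysics (heterogenized)
struct CellP {
  double gL, gK, gNa, gCa, gahp, gT, vL, vK, vNa, vCa;
};

// splitmix64 for per-neuron RNG stream seeding
static inline uint64_t splitmix64(uint64_t& x) {
  x += 0x9E3779B97f4A7C15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Rng {
  uint64_t s;
  inline double unif() {  // xorshift64*
    s ^= s >> 12; s ^= s << 25; s ^= s >> 27;
    return (double)((s * 0x2545F4914F6CDD1DULL) >> 11) * (1.0 / 9007199254740992.0);
  }
  inline double expdraw() {
    double u = unif();
    if (u <= 0) u = 1e-300;
    return -std::log(u);
  }
};

// Fehlberg 4(5) tableau
static const double C2 = 0.25, C3 = 0.375, C4 = 12.0 / 13.0, C5 = 1.0, C6 = 0.5;
static const double A21 = 0.25;
static const double A31 = 3.0 / 32, A32 = 9.0 / 32;
static const double A41 = 1932.0 / 2197, A42 = -7200.0 / 2197, A43 = 7296.0 / 2197;
static const double A51 = 439.0 / 216, A52 = -8.0, A53 = 3680.0 / 513, A54 = -845.0 / 4104;
static const double A61 = -8.0 / 27, A62 = 2.0, A63 = -3544.0 / 2565, A64 = 1859.0 / 4104,
                    A65 = -11.0 / 40;
static const double B41 = 25.0 / 216, B43 = 1408.0 / 2565, B44 = 2197.0 / 4104, B45 = -0.2;
static const double B51 = 16.0 / 135, B53 = 6656.0 / 12825, B54 = 28561.0 / 56430,
                    B55 = -9.0 / 50, B56 = 2.0 / 55;

constexpr int NSTATE = 5;   // v n h r Ca
constexpr int NSLOT = 3;    // kernel slots: intra+inter network classes + noise

struct Engine {
  int n_stn, n, n_steps;
  double h_grid;
  // state
  std::vector<double> y;           // n x 5
  std::vector<double> kz, ka;      // n x NSLOT
  std::vector<double> slot_tau, slot_vsyn;  // n x NSLOT (values per kind)
  std::vector<CellP> cp;
  std::vector<int> kind;           // 0 STN 1 GPe
  KindTables tab[2];
  // decay tables for e^{-s/tau} over s in [0, h_grid]
  Lut dec[2];                      // per distinct tau index
  std::vector<int> slot_tau_idx;   // n x NSLOT -> 0/1
  double taus[2];

  // per-neuron stimulation gain per contact (STN only), I_stim scratch
  std::vector<double> stim_gain;   // n_stn x M
  int M = 0;
  std::vector<double> I_stim;      // n
  std::vector<double> I_noise_w;   // per neuron noise weight
  std::vector<double> noise_rate;  // per neuron events/ms
  std::vector<double> next_noise;
  std::vector<Rng> rng;

  // integration control
  double atol, rtol;
  std::vector<double> hstep;

  inline double gate_drv(const KindTables& T, double phi, double xinf, double x,
                         double tau) const {
    return phi * (xinf - x) / tau;
  }

  // derivative of neuron i at offset s inside current interval
  inline void deriv(int i, double s, const double* yy, double* dy,
                    double Istim_i) const {
    const KindTables& T = tab[kind[i]];
    const CellP& P = cp[i];
    double v = yy[0], nn = yy[1], hh = yy[2], rr = yy[3], Ca = yy[4];
    double minf = T.minf.eval(v);
    double IL = P.gL * (v - P.vL);
    double n2 = nn * nn;
    double IK = P.gK * n2 * n2 * (v - P.vK);
    double INa = P.gNa * minf * minf * minf * hh * (v - P.vNa);
    double ainf = T.ainf.eval(v);
    double IT;
    if (T.has_b) {
      double b = T.binf.eval(rr);
      IT = P.gT * ainf * ainf * ainf * b * b * (v - P.vCa);
    } else {
      IT = P.gT * ainf * ainf * ainf * rr * (v - P.vCa);
    }
    double sinf = T.sinf.eval(v);
    double ICa = P.gCa * sinf * sinf * hh * (v - P.vCa);
    double Iahp = P.gahp * (v - P.vK) * Ca / (Ca + T.k1);
    // synaptic kernels at offset s (analytic)
    double Isyn = 0.0;
    const double* z = &kz[(size_t)i * NSLOT];
    const double* a = &ka[(size_t)i * NSLOT];
    for (int q = 0; q < NSLOT; ++q) {
      int ti = slot_tau_idx[(size_t)i * NSLOT + q];
      double tau = taus[ti];
      double E = dec[ti].eval(s);
      double as = E * (a[q] + z[q] * s / tau);
      Isyn += (v - slot_vsyn[(size_t)i * NSLOT + q]) * as / tau;
    }
    dy[0] = (-IL - IK - INa - IT - ICa - Iahp - Isyn + Istim_i + T.I_app) / T.c_m;
    dy[1] = T.phi_n * (T.ninf.eval(v) - nn) / T.taun.eval(v);
    dy[2] = T.phi_h * (T.hinf.eval(v) - hh) / T.tauh.eval(v);
    dy[3] = T.phi_r * (T.rinf.eval(v) - rr) / T.taur.eval(v);
    dy[4] = T.eps * (-ICa - IT - T.k_Ca * Ca);
  }

  // advance neuron i over [0, h_grid] adaptively; returns false on
  // step-size underflow
  bool integrate_interval(int i, double Istim_i) {
    double* Y = &y[(size_t)i * NSTATE];
    double s = 0.0;
    double h = hstep[i];
    double k1v[NSTATE], k2v[NSTATE], k3v[NSTATE], k4v[NSTATE], k5v[NSTATE],
        k6v[NSTATE], yt[NSTATE], y4[NSTATE], y5[NSTATE];
    int guard = 0;
    while (s < h_grid * (1.0 - 1e-12)) {
      if (++guard > 100000) return false;
      double rem = h_grid - s;
      if (h < 1e-10) return false;  // genuine step-size underflow
      double h_full = h;            // error-controlled proposal
      if (h > rem) h = rem;
      deriv(i, s, Y, k1v, Istim_i);
      for (int j = 0; j < NSTATE; ++j) yt[j] = Y[j] + h * A21 * k1v[j];
      deriv(i, s + C2 * h, yt, k2v, Istim_i);
      for (int j = 0; j < NSTATE; ++j)
        yt[j] = Y[j] + h * (A31 * k1v[j] + A32 * k2v[j]);
      deriv(i, s + C3 * h, yt, k3v, Istim_i);
      for (int j = 0; j < NSTATE; ++j)
        yt[j] = Y[j] + h * (A41 * k1v[j] + A42 * k2v[j] + A43 * k3v[j]);
      deriv(i, s + C4 * h, yt, k4v, Istim_i);
      for (int j = 0; j < NSTATE; ++j)
        yt[j] = Y[j] + h * (A51 * k1v[j] + A52 * k2v[j] + A53 * k3v[j] + A54 * k4v[j]);
      deriv(i, s + C5 * h, yt, k5v, Istim_i);
      for (int j = 0; j < NSTATE; ++j)
        yt[j] = Y[j] + h * (A61 * k1v[j] + A62 * k2v[j] + A63 * k3v[j] +
                            A64 * k4v[j] + A65 * k5v[j]);
      deriv(i, s + C6 * h, yt, k6v, Istim_i);
      double err = 0.0;
      for (int j = 0; j < NSTATE; ++j) {
        y4[j] = Y[j] + h * (B41 * k1v[j] + B43 * k3v[j] + B44 * k4v[j] + B45 * k5v[j]);
        y5[j] = Y[j] + h * (B51 * k1v[j] + B53 * k3v[j] + B54 * k4v[j] +
                            B55 * k5v[j] + B56 * k6v[j]);
        double sc = atol + rtol * std::max(std::fabs(Y[j]), std::fabs(y5[j]));
        double e = std::fabs(y5[j] - y4[j]) / sc;
        if (e > err) err = e;
      }
      if (err <= 1.0) {
        s += h;
        for (int j = 0; j < NSTATE; ++j) Y[j] = y5[j];
        // hard projection of gating variables and calcium
        for (int j = 1; j <= 3; ++j) {
          if (Y[j] < 0) Y[j] = 0;
          else if (Y[j] > 1) Y[j] = 1;
        }
        if (Y[4] < 0) Y[4] = 0;
        double fac = (err > 1e-12) ? 0.9 * std::pow(err, -0.2) : 2.0;
        if (fac > 2.0) fac = 2.0;
        h = h_full * fac;  // controller proposal ignores interval clamping
        if (h > h_grid) h = h_grid;
      } else {
        double fac = 0.9 * std::pow(err, -0.2);
        if (fac < 0.2) fac = 0.2;
        h *= fac;
      }
      if (!std::isfinite(Y[0])) return false;
    }
    hstep[i] = std::min(h, h_grid);
    return true;
  }

  void advance_kernels() {
    double E[2], W[2];
    for (int ti = 0; ti < 2; ++ti) {
      E[ti] = std::exp(-h_grid / taus[ti]);
      W[ti] = h_grid / taus[ti];
    }
    for (int i = 0; i < n; ++i) {
      double* z = &kz[(size_t)i * NSLOT];
      double* a = &ka[(size_t)i * NSLOT];
      for (int q = 0; q < NSLOT; ++q) {
        int ti = slot_tau_idx[(size_t)i * NSLOT + q];
        a[q] = E[ti] * (a[q] + z[q] * W[ti]);
        z[q] *= E[ti];
      }
    }
  }
};

}  // namespace

// [[Rcpp::export(name = ".engine_run")]]
List engine_run(List sys, List cfg) {
  Engine eng;
  eng.n_stn = as<int>(sys["n_stn"]);
  eng.n = as<int>(sys["n"]);
  const int n = eng.n, n_stn = eng.n_stn;
  eng.h_grid = as<double>(cfg["dt_event"]);
  const double t_end = as<double>(cfg["duration"]);
  eng.n_steps = (int)std::llround(t_end / eng.h_grid);
  eng.atol = as<double>(cfg["abs_tol"]);
  eng.rtol = as<double>(cfg["rel_tol"]);
  const double thresh = as<double>(cfg["spike_threshold"]);
  const double record_dt = as<double>(cfg["record_dt"]);
  const int rec_every = std::max(1, (int)std::llround(record_dt / eng.h_grid));
  const uint64_t seed = (uint64_t)as<double>(cfg["seed"]);

  // --- tables ---
  List tabs = sys["tables"];
  for (int kd = 0; kd < 2; ++kd) {
    List T = tabs[kd];
    double v0 = as<double>(T["v0"]), dv = as<double>(T["dv"]);
    NumericMatrix G = T["gates"];  // cols: minf hinf ninf rinf ainf sinf tauh taun taur
    KindTables& K = eng.tab[kd];
    auto col = [&](int j) {
      NumericVector v(G.nrow());
      for (int r = 0; r < G.nrow(); ++r) v[r] = G(r, j);
      return make_lut(v, v0, dv);
    };
    K.minf = col(0); K.hinf = col(1); K.ninf = col(2); K.rinf = col(3);
    K.ainf = col(4); K.sinf = col(5); K.tauh = col(6); K.taun = col(7);
    K.taur = col(8);
    if (T.containsElementNamed("b_table")) {
      List B = T["b_table"];
      K.binf = make_lut(B["y"], as<double>(B["x0"]), as<double>(B["dx"]));
      K.has_b = true;
    }
    K.phi_h = as<double>(T["phi_h"]);
    K.phi_n = as<double>(T["phi_n"]);
    K.phi_r = as<double>(T["phi_r"]);
    K.k1 = as<double>(T["k1"]);
    K.k_Ca = as<double>(T["k_Ca"]);
    K.eps = as<double>(T["eps"]);
    K.c_m = as<double>(T["c_m"]);
    K.I_app = as<double>(T["I_app"]);
  }

  // --- per-neuron params & state ---
  NumericMatrix pm = sys["cell_params"];  // n x 10
  eng.cp.resize(n);
  for (int i = 0; i < n; ++i) {
    CellP& P = eng.cp[i];
    P.gL = pm(i, 0); P.gK = pm(i, 1); P.gNa = pm(i, 2); P.gCa = pm(i, 3);
    P.gahp = pm(i, 4); P.gT = pm(i, 5); P.vL = pm(i, 6); P.vK = pm(i, 7);
    P.vNa = pm(i, 8); P.vCa = pm(i, 9);
  }
  eng.kind.resize(n);
  for (int i = 0; i < n; ++i) eng.kind[i] = (i < n_stn) ? 0 : 1;
  NumericMatrix y0 = sys["state0"];  // n x 5
  eng.y.assign(n * NSTATE, 0.0);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < NSTATE; ++j) eng.y[(size_t)i * NSTATE + j] = y0(i, j);

  // --- kernel slots ---
  // slot 0: intra/inter excitatory class targeting this kind
  //   (STN <- ss: tau 1.0, v 0 ; GPe <- sg: tau 1.0, v 0)
  // slot 1: inhibitory class (STN <- gs: tau 3.3, v -100 ; GPe <- gg: 3.3, -80)
  // slot 2: noise (tau 1.0, v 0)
  List slots = sys["slots"];  // list of 2 (per kind): tau[3], vsyn[3]
  eng.taus[0] = 1.0;
  eng.taus[1] = 3.3;
  {
    NumericVector taus_in = sys["kernel_taus"];
    eng.taus[0] = taus_in[0];
    eng.taus[1] = taus_in[1];
  }
  eng.slot_tau.assign((size_t)n * NSLOT, 1.0);
  eng.slot_vsyn.assign((size_t)n * NSLOT, 0.0);
  eng.slot_tau_idx.assign((size_t)n * NSLOT, 0);
  for (int i = 0; i < n; ++i) {
    List S = slots[eng.kind[i]];
    NumericVector st = S["tau_idx"], sv = S["v_syn"];
    for (int q = 0; q < NSLOT; ++q) {
      eng.slot_tau_idx[(size_t)i * NSLOT + q] = (int)st[q];
      eng.slot_tau[(size_t)i * NSLOT + q] = eng.taus[(int)st[q]];
      eng.slot_vsyn[(size_t)i * NSLOT + q] = sv[q];
    }
  }
  // decay tables e^{-s/tau}, s in [0, h_grid]
  for (int ti = 0; ti < 2; ++ti) {
    int m = 512;
    NumericVector vals(m);
    for (int k = 0; k < m; ++k)
      vals[k] = std::exp(-(eng.h_grid * k / (m - 1)) / eng.taus[ti]);
    eng.dec[ti] = make_lut(vals, 0.0, eng.h_grid / (m - 1));
  }

  // --- edges (CSR by global pre id); class meta: target slot, gain ---
  List edges = sys["edges"];  // per class: pre, post (0-based global), weight, slot, gain, delay
  const int n_class = edges.size();
  std::vector<std::vector<int>> e_pre(n_class);
  std::vector<std::vector<int>> e_post(n_class);
  std::vector<std::vector<double>> e_w(n_class);
  std::vector<std::vector<int>> e_start(n_class);
  std::vector<int> e_slot(n_class);
  std::vector<double> e_gain(n_class);
  std::vector<int> e_delay_steps(n_class);
  std::vector<bool> e_plastic(n_class);
  int ss_idx = -1;
  for (int c = 0; c < n_class; ++c) {
    List E = edges[c];
    IntegerVector pre = E["pre"], post = E["post"];
    NumericVector w = E["weight"];
    e_slot[c] = as<int>(E["slot"]);
    e_gain[c] = as<double>(E["gain"]);
    e_delay_steps[c] = (int)std::llround(as<double>(E["delay"]) / eng.h_grid);
    e_plastic[c] = as<bool>(E["plastic"]);
    if (e_plastic[c]) ss_idx = c;
    int m = pre.size();
    // counting sort by pre (inputs are grouped by pre already, but be safe)
    std::vector<int> cnt(n + 1, 0);
    for (int k = 0; k < m; ++k) cnt[pre[k] + 1]++;
    for (int i = 0; i < n; ++i) cnt[i + 1] += cnt[i];
    e_start[c].assign(cnt.begin(), cnt.end());
    e_post[c].resize(m);
    e_pre[c].resize(m);
    e_w[c].resize(m);
    std::vector<int> pos(cnt.begin(), cnt.end() - 1);
    for (int k = 0; k < m; ++k) {
      int p = pre[k];
      int at = pos[p]++;
      e_pre[c][at] = p;
      e_post[c][at] = post[k];
      e_w[c][at] = w[k];
    }
  }

  // in-CSR for the plastic class (potentiation pass needs in-edges)
  std::vector<int> in_start, in_eidx;
  if (ss_idx >= 0) {
    const std::vector<int>& post = e_post[ss_idx];
    int m = post.size();
    std::vector<int> cnt(n + 1, 0);
    for (int k = 0; k < m; ++k) cnt[post[k] + 1]++;
    for (int i = 0; i < n; ++i) cnt[i + 1] += cnt[i];
    in_start = cnt;
    in_eidx.resize(m);
    std::vector<int> pos(cnt.begin(), cnt.end() - 1);
    for (int k = 0; k < m; ++k) in_eidx[pos[post[k]]++] = k;
  }

  // --- STDP ---
  List stdp = sys["stdp"];
  const bool plast_on = as<bool>(stdp["enabled"]) && ss_idx >= 0;
  const double lam = as<double>(stdp["lam"]);
  const double beta = as<double>(stdp["beta"]);
  const double tau_p = as<double>(stdp["tau_plus"]);
  const double tau_m = as<double>(stdp["tau_minus"]);
  const double w_max = as<double>(stdp["w_max"]);
  const double dec_p = std::exp(-eng.h_grid / tau_p);
  const double dec_m = std::exp(-eng.h_grid / tau_m);
  std::vector<double> x_pre(n_stn, 0.0), x_post(n_stn, 0.0);
  double ss_sum = 0.0;
  int ss_m = 0;
  if (ss_idx >= 0) {
    for (double w : e_w[ss_idx]) ss_sum += w;
    ss_m = e_w[ss_idx].size();
  }

  // --- noise ---
  List noise = sys["noise"];
  NumericVector nz_rate = noise["rate_per_ms"];  // per neuron
  NumericVector nz_w = noise["w_noise"];         // per neuron
  eng.rng.resize(n);
  eng.next_noise.resize(n);
  for (int i = 0; i < n; ++i) {
    uint64_t s0 = seed * 0x9E3779B97f4A7C15ULL + (uint64_t)(i + 1);
    eng.rng[i].s = splitmix64(s0) | 1ULL;
    for (int k = 0; k < 8; ++k) eng.rng[i].unif();  // warm up
    eng.next_noise[i] =
        nz_rate[i] > 0 ? eng.rng[i].expdraw() / nz_rate[i] : 1e300;
  }

  // --- stimulation ---
  bool stim_on = false;
  std::vector<double> sgain;  // n_stn x M
  std::vector<long long> p_onset_step;
  std::vector<int> p_contact;
  double kappa = 0, omega = 0, p_s = 8;
  int Mc = 0, cath_steps = 0, full_steps = 0;
  if (sys.containsElementNamed("stim") && !Rf_isNull(sys["stim"])) {
    List st = sys["stim"];
    NumericMatrix G = st["gains"];  // n_stn x M
    Mc = G.ncol();
    sgain.resize((size_t)n_stn * Mc);
    for (int i = 0; i < n_stn; ++i)
      for (int j = 0; j < Mc; ++j) sgain[(size_t)i * Mc + j] = G(i, j);
    NumericVector ons = st["onset"];
    IntegerVector con = st["contact"];
    for (int k = 0; k < ons.size(); ++k) {
      p_onset_step.push_back((long long)std::llround(ons[k] / eng.h_grid));
      p_contact.push_back(con[k] - 1);
    }
    kappa = as<double>(st["kappa"]);
    omega = as<double>(st["omega"]);
    p_s = as<double>(st["p_s"]);
    cath_steps = std::max(1, (int)std::llround(omega / eng.h_grid));
    full_steps = std::max(cath_steps + 1,
                          (int)std::llround(omega * (1.0 + p_s) / eng.h_grid));
    stim_on = true;
  }
  eng.I_stim.assign(n, 0.0);

  // --- spike bookkeeping ---
  const int delay_steps_max =
      n_class ? *std::max_element(e_delay_steps.begin(), e_delay_steps.end()) : 1;
  const int ring = delay_steps_max + 2;
  std::vector<std::vector<int>> delivery(ring);
  // STDP pairing uses the dendritic-delay convention: the somatic post
  // spike reaches the synapse one full transmission delay late, so
  // dt = (t_post + d) - t_pre and synchronous volleys pair at +d
  // (potentiation). Post-side plasticity events are therefore delayed
  // through their own ring.
  std::vector<std::vector<int>> post_ring(ring);
  const int d_ss = (ss_idx >= 0) ? e_delay_steps[ss_idx] : 1;
  std::vector<double> v_prev(n), v_prev2(n);
  for (int i = 0; i < n; ++i) v_prev[i] = v_prev2[i] = eng.y[(size_t)i * NSTATE];
  std::vector<int> sp_id;
  std::vector<double> sp_t;

  // --- recorders ---
  IntegerVector rec_ids;
  if (cfg.containsElementNamed("record_ids") && !Rf_isNull(cfg["record_ids"]))
    rec_ids = cfg["record_ids"];
  const int n_rec_steps = eng.n_steps / rec_every;
  NumericVector rec_t(n_rec_steps), mv_stn(n_rec_steps), mv_gpe(n_rec_steps),
      mw_ss(n_rec_steps);
  NumericMatrix vtr(rec_ids.size() > 0 ? n_rec_steps : 0, rec_ids.size());

  eng.hstep.assign(n, eng.h_grid * 0.5);
  eng.kz.assign((size_t)n * NSLOT, 0.0);
  eng.ka.assign((size_t)n * NSLOT, 0.0);

  int stim_ptr = 0;
  int rec_k = 0;
  bool failed = false;
  int failed_id = -1;

  for (int step = 0; step < eng.n_steps && !failed; ++step) {
    const double t = step * eng.h_grid;

    // ---- spike detection at previous sample (local max above threshold)
    std::vector<int>* due = &delivery[step % ring];
    std::vector<int>* post_due = &post_ring[step % ring];
    std::vector<int> stn_spikers;
    if (step >= 2) {
      for (int i = 0; i < n; ++i) {
        double vm = v_prev[i];
        if (vm > thresh && vm >= v_prev2[i] && vm > eng.y[(size_t)i * NSTATE]) {
          sp_id.push_back(i + 1);
          sp_t.push_back(t - eng.h_grid);
          int dstep = step - 1;
          for (int c = 0; c < n_class; ++c)
            if (e_start[c][i + 1] > e_start[c][i])
              delivery[(dstep + e_delay_steps[c]) % ring].push_back(c * n + i);
          if (plast_on && i < n_stn) {
            stn_spikers.push_back(i);
            post_ring[(dstep + d_ss) % ring].push_back(i);
          }
        }
      }
    }
    // shift detection samples (y currently holds the sample at t)
    for (int i = 0; i < n; ++i) {
      v_prev2[i] = v_prev[i];
      v_prev[i] = eng.y[(size_t)i * NSTATE];
    }

    // ---- STDP (dendritic-delay pairing)
    if (plast_on) {
      for (int i = 0; i < n_stn; ++i) {
        x_pre[i] *= dec_p;
        x_post[i] *= dec_m;
      }
      // back-propagated post spikes arriving at the synapse now:
      // potentiate in-edges from pre traces (which exclude this step's
      // pre emissions, so dt = 0 never potentiates), then bump the
      // delayed post trace
      for (int j : *post_due) {
        for (int k = in_start[j]; k < in_start[j + 1]; ++k) {
          int e = in_eidx[k];
          double w = e_w[ss_idx][e];
          double nw = w + lam * x_pre[e_pre[ss_idx][e]];
          if (nw > w_max) nw = w_max;
          ss_sum += nw - w;
          e_w[ss_idx][e] = nw;
        }
      }
      for (int j : *post_due) x_post[j] += 1.0;
      post_due->clear();
      // pre emissions this step: depress out-edges against the delayed
      // post trace (which includes this step's post arrivals: exact
      // coincidences depress once), then bump the pre trace
      for (int i : stn_spikers) {
        for (int k = e_start[ss_idx][i]; k < e_start[ss_idx][i + 1]; ++k) {
          int j = e_post[ss_idx][k];
          double w = e_w[ss_idx][k];
          double nw = w - lam * beta * x_post[j];
          if (nw < 0) nw = 0;
          ss_sum += nw - w;
          e_w[ss_idx][k] = nw;
        }
      }
      for (int i : stn_spikers) x_pre[i] += 1.0;
    }

    // ---- process synaptic arrivals due at this step (kernel injection)
    for (int enc : *due) {
      int c = enc / n, i = enc % n;
      for (int k = e_start[c][i]; k < e_start[c][i + 1]; ++k)
        eng.kz[(size_t)e_post[c][k] * NSLOT + e_slot[c]] += e_gain[c] * e_w[c][k];
    }
    due->clear();

    // ---- noise arrivals in [t, t+h): inject at interval start
    for (int i = 0; i < n; ++i) {
      while (eng.next_noise[i] < t + eng.h_grid) {
        eng.kz[(size_t)i * NSLOT + 2] += nz_w[i];
        eng.next_noise[i] += eng.rng[i].expdraw() / nz_rate[i];
      }
    }

    // ---- stimulation amplitude for this interval
    if (stim_on) {
      std::fill(eng.I_stim.begin(), eng.I_stim.begin() + n_stn, 0.0);
      while (stim_ptr < (int)p_onset_step.size() &&
             p_onset_step[stim_ptr] + full_steps <= step)
        ++stim_ptr;
      for (int q = stim_ptr; q < (int)p_onset_step.size(); ++q) {
        long long rel = step - p_onset_step[q];
        if (rel < 0) break;
        double amp;
        if (rel < cath_steps) amp = kappa;
        else if (rel < full_steps) amp = -kappa / p_s;
        else continue;
        int cj = p_contact[q];
        for (int i = 0; i < n_stn; ++i)
          eng.I_stim[i] += sgain[(size_t)i * Mc + cj] * amp;
      }
    }

    // ---- integrate all neurons over the interval
    for (int i = 0; i < n; ++i) {
      double Ist = (stim_on && i < n_stn) ? eng.I_stim[i] : 0.0;
      if (!eng.integrate_interval(i, Ist)) {
        failed = true;
        failed_id = i + 1;
        break;
      }
    }
    if (failed) break;
    eng.advance_kernels();

    // ---- record
    if ((step + 1) % rec_every == 0 && rec_k < n_rec_steps) {
      double s1 = 0, s2 = 0;
      for (int i = 0; i < n_stn; ++i) s1 += eng.y[(size_t)i * NSTATE];
      for (int i = n_stn; i < n; ++i) s2 += eng.y[(size_t)i * NSTATE];
      rec_t[rec_k] = t + eng.h_grid;
      mv_stn[rec_k] = n_stn ? s1 / n_stn : NA_REAL;
      mv_gpe[rec_k] = (n > n_stn) ? s2 / (n - n_stn) : NA_REAL;
      mw_ss[rec_k] = ss_m ? ss_sum / ss_m : NA_REAL;
      for (int q = 0; q < rec_ids.size(); ++q)
        vtr(rec_k, q) = eng.y[(size_t)(rec_ids[q] - 1) * NSTATE];
      ++rec_k;
    }
    if (step % 20000 == 0) Rcpp::checkUserInterrupt();
  }

  if (failed) {
    const double* Y = &eng.y[(size_t)(failed_id - 1) * NSTATE];
    stop("integration failed (step-size underflow or non-finite state) at neuron %d "
         "[v=%g n=%g h=%g r=%g Ca=%g]",
         failed_id, Y[0], Y[1], Y[2], Y[3], Y[4]);
  }

  NumericMatrix yout(n, NSTATE);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < NSTATE; ++j) yout(i, j) = eng.y[(size_t)i * NSTATE + j];
  NumericVector w_ss_out;
  if (ss_idx >= 0) w_ss_out = NumericVector(e_w[ss_idx].begin(), e_w[ss_idx].end());

  return List::create(
      _["spike_id"] = IntegerVector(sp_id.begin(), sp_id.end()),
      _["spike_t"] = NumericVector(sp_t.begin(), sp_t.end()),
      _["rec_t"] = rec_t, _["mean_v_stn"] = mv_stn, _["mean_v_gpe"] = mv_gpe,
      _["mean_w_ss"] = mw_ss, _["v_traces"] = vtr, _["state"] = yout,
      _["w_ss"] = w_ss_out);
}
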