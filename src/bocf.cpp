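#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Four-variable minimal ventricular (Bueno-Orovio--Cherry--Fenton) model with
// the fibrosis-remodelled parameter set, plus a second-order Rush--Larsen
// integrator usable per node inside the tissue solver and for single cells.
//
// Symbol mapping from the parameter table onto the minimal-model formulas:
//   u_v  -> theta_v      (fast-gate Heaviside threshold)
//   uv_m -> theta_v^-    (v-gate time-constant switch / v_inf threshold)
//   u_w  -> theta_w      (slow-current Heaviside threshold)
//   u_o  -> theta_o      (ungated-current / w_inf switch)
//   uw_m, kw_m           (midpoint / steepness of the tau_w^- sigmoid)
//   u_so, k_so           (midpoint / steepness of the tau_so sigmoid)
//   u_s,  k_s            (midpoint / steepness of the s-gate steady state)
//   w_inf_star           (w_inf plateau value above theta_o)
// Heaviside convention: H(0) = 1.

struct BOCF {
  double Cm;
  double uv, uvm, uw, uwm, uo, us, uso, uu, winf_star;
  double tvp, tv1m, tv2m, twp, tw1m, tw2m, twinf;
  double to1, to2, ts1, ts2, tfi, tsi, tso1, tso2;
  double ks, kwm, kso;
};

static BOCF as_bocf(const NumericVector& p) {
  BOCF b;
  b.Cm   = p["C_m"];
  b.uv   = p["u_v"];   b.uvm = p["uv_minus"]; b.uw  = p["u_w"];
  b.uwm  = p["uw_minus"]; b.uo = p["u_o"];    b.us  = p["u_s"];
  b.uso  = p["u_so"];  b.uu  = p["u_u"];      b.winf_star = p["w_inf_star"];
  b.tvp  = p["tau_v_plus"]; b.tv1m = p["tau_v1_minus"]; b.tv2m = p["tau_v2_minus"];
  b.twp  = p["tau_w_plus"]; b.tw1m = p["tau_w1_minus"]; b.tw2m = p["tau_w2_minus"];
  b.twinf = p["tau_w_inf"];
  b.to1  = p["tau_o1"]; b.to2 = p["tau_o2"];
  b.ts1  = p["tau_s1"]; b.ts2 = p["tau_s2"];
  b.tfi  = p["tau_fi"]; b.tsi = p["tau_si"];
  b.tso1 = p["tau_so1"]; b.tso2 = p["tau_so2"];
  b.ks   = p["k_s"]; b.kwm = p["kw_minus"]; b.kso = p["k_so"];
  return b;
}

static inline double heav(double x) { return x >= 0.0 ? 1.0 : 0.0; }

struct Rates {
  double jfi, jso, jsi;      // ionic currents
  double Av, Bv, Aw, Bw, As, Bs; // gate ODEs dy/dt = A - B*y
  double du;                 // -(Jfi+Jso+Jsi)/Cm (no stimulus)
};

static inline Rates rates_at(double u, double v, double w, double s, const BOCF& b) {
  Rates r;
  const double Hv  = heav(u - b.uv);
  const double Hw  = heav(u - b.uw);
  const double Ho  = heav(u - b.uo);
  // the v-gate switch treats the boundary as resting (strict inequality):
  // the remodelled rest state sits exactly at u = u_o = theta_v^-, and must
  // keep v_inf = 1 there to remain excitable
  const double Hvm = (u > b.uvm) ? 1.0 : 0.0;

  const double tau_vm = (1.0 - Hvm) * b.tv1m + Hvm * b.tv2m;
  const double tau_wm = b.tw1m + (b.tw2m - b.tw1m) * 0.5 * (1.0 + std::tanh(b.kwm * (u - b.uwm)));
  const double tau_so = b.tso1 + (b.tso2 - b.tso1) * 0.5 * (1.0 + std::tanh(b.kso * (u - b.uso)));
  const double tau_s  = (1.0 - Hw) * b.ts1 + Hw * b.ts2;
  const double tau_o  = (1.0 - Ho) * b.to1 + Ho * b.to2;

  const double v_inf = (u < b.uvm) ? 1.0 : 0.0;
  const double w_inf = (1.0 - Ho) * (1.0 - u / b.twinf) + Ho * b.winf_star;
  const double s_inf = 0.5 * (1.0 + std::tanh(b.ks * (u - b.us)));

  r.Av = (1.0 - Hv) * v_inf / tau_vm;
  r.Bv = (1.0 - Hv) / tau_vm + Hv / b.tvp;
  r.Aw = (1.0 - Hw) * w_inf / tau_wm;
  r.Bw = (1.0 - Hw) / tau_wm + Hw / b.twp;
  r.As = s_inf / tau_s;
  r.Bs = 1.0 / tau_s;

  r.jfi = -v * Hv * (u - b.uv) * (b.uu - u) / b.tfi;
  r.jso = (u - b.uo) * (1.0 - Hw) / tau_o + Hw / tau_so;
  r.jsi = -Hw * w * s / b.tsi;
  r.du  = -(r.jfi + r.jso + r.jsi) / b.Cm;
  return r;
}

// Rush--Larsen gate update: exact solve of dy/dt = A - B*y over dt with frozen A,B
static inline double rl_gate(double y, double A, double B, double dt) {
  const double yss = A / B;
  return yss + (y - yss) * std::exp(-B * dt);
}

// One second-order (midpoint) Rush--Larsen step for a single state.
static inline void srl2_step(double& u, double& v, double& w, double& s,
                             const BOCF& b, double dt, double istim) {
  // predictor: half step with coefficients frozen at the current state
  Rates r0 = rates_at(u, v, w, s, b);
  double uh = u + 0.5 * dt * (r0.du + istim);
  double vh = rl_gate(v, r0.Av, r0.Bv, 0.5 * dt);
  double wh = rl_gate(w, r0.Aw, r0.Bw, 0.5 * dt);
  double sh = rl_gate(s, r0.As, r0.Bs, 0.5 * dt);
  // corrector: full step from the original state with midpoint coefficients
  Rates rm = rates_at(uh, vh, wh, sh, b);
  u = u + dt * (rm.du + istim);
  v = rl_gate(v, rm.Av, rm.Bv, dt);
  w = rl_gate(w, rm.Aw, rm.Bw, dt);
  s = rl_gate(s, rm.As, rm.Bs, dt);
}

// [[Rcpp::export]]
List cpp_ionic_current(NumericVector state, NumericVector params) {
  double u = state[0], v = state[1], w = state[2], s = state[3];
  if (!R_finite(u) || !R_finite(v) || !R_finite(w) || !R_finite(s))
    stop("non-finite cell state: solver divergence");
  BOCF b = as_bocf(params);
  Rates r = rates_at(u, v, w, s, b);
  return List::create(_["J_fi"] = r.jfi, _["J_so"] = r.jso,
                      _["J_si"] = r.jsi, _["J_total"] = r.jfi + r.jso + r.jsi);
}

// [[Rcpp::export]]
NumericVector cpp_step_cell(NumericVector state, NumericVector params,
                            double dt, double istim) {
  double u = state[0], v = state[1], w = state[2], s = state[3];
  if (!R_finite(u) || !R_finite(v) || !R_finite(w) || !R_finite(s))
    stop("non-finite cell state: solver divergence");
  BOCF b = as_bocf(params);
  srl2_step(u, v, w, s, b, dt, istim);
  return NumericVector::create(_["u"] = u, _["v"] = v, _["w"] = w, _["s"] = s);
}

// [[Rcpp::export]]
NumericMatrix cpp_simulate_cell(NumericVector params, double dt, int n_steps,
                                double stim_amplitude, double stim_duration) {
  BOCF b = as_bocf(params);
  double u = 0.0, v = 1.0, w = 1.0, s = 0.0;
  NumericMatrix out(n_steps + 1, 4);
  out(0, 0) = u; out(0, 1) = v; out(0, 2) = w; out(0, 3) = s;
  for (int k = 0; k < n_steps; ++k) {
    double t = k * dt;
    double istim = (t < stim_duration) ? stim_amplitude : 0.0;
    srl2_step(u, v, w, s, b, dt, istim);
    if (!R_finite(u)) stop("non-finite potential at step %d", k + 1);
    out(k + 1, 0) = u; out(k + 1, 1) = v; out(k + 1, 2) = w; out(k + 1, 3) = s;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Sparse kernels for the tissue solver.  All matrices arrive in
// compressed-sparse-column form restricted to active nodes.

static inline void csc_mult(const IntegerVector& Ap, const IntegerVector& Ai,
                            const NumericVector& Ax, const std::vector<double>& x,
                            std::vector<double>& y) {
  const int n = Ap.size() - 1;
  std::fill(y.begin(), y.end(), 0.0);
  for (int j = 0; j < n; ++j) {
    const double xj = x[j];
    if (xj == 0.0) continue;
    for (int p = Ap[j]; p < Ap[j + 1]; ++p) y[Ai[p]] += Ax[p] * xj;
  }
}

// forward solve L y = b with L lower-triangular CSC (unit diagonal NOT assumed)
static inline void csc_lsolve(const IntegerVector& Lp, const IntegerVector& Li,
                              const NumericVector& Lx, std::vector<double>& x) {
  const int n = Lp.size() - 1;
  for (int j = 0; j < n; ++j) {
    x[j] /= Lx[Lp[j]];           // diagonal is the first entry of each column
    const double xj = x[j];
    for (int p = Lp[j] + 1; p < Lp[j + 1]; ++p) x[Li[p]] -= Lx[p] * xj;
  }
}

// backward solve L' x = b using the same CSC storage of L
static inline void csc_ltsolve(const IntegerVector& Lp, const IntegerVector& Li,
                               const NumericVector& Lx, std::vector<double>& x) {
  const int n = Lp.size() - 1;
  for (int j = n - 1; j >= 0; --j) {
    double acc = x[j];
    for (int p = Lp[j] + 1; p < Lp[j + 1]; ++p) acc -= Lx[p] * x[Li[p]];
    x[j] = acc / Lx[Lp[j]];
  }
}

// Monodomain time loop (operator splitting):
//   reaction: one SRL2 step per active node
//   diffusion: Crank--Nicolson with consistent mass,
//     (M + dt/2 K) u1 = (M - dt/2 K) u0, pre-factorised as P'(LL')P.
// Records threshold crossings (activation upward, repolarisation downward)
// with a refractory lockout, flags re-entry as a second activation of any
// boundary node, and stops on quiescence or t_max.
// [[Rcpp::export]]
List cpp_run_monodomain(NumericVector params,
                        IntegerVector Bp, IntegerVector Bi, NumericVector Bx,
                        IntegerVector Lp, IntegerVector Li, NumericVector Lx,
                        IntegerVector perm,            // 0-based: (P b)[i] = b[perm[i]]
                        IntegerVector stim_nodes,      // 0-based active-node indices
                        double stim_start, double stim_duration, double stim_amplitude,
                        LogicalVector boundary,        // per active node
                        double dt, double t_max,
                        double threshold, double lockout_ms,
                        double quiescence_u, int check_every,
                        bool stop_on_reentry) {
  BOCF b = as_bocf(params);
  const int n = Bp.size() - 1;
  std::vector<double> u(n, 0.0), v(n, 1.0), w(n, 1.0), s(n, 0.0);
  std::vector<double> rhs(n), tmp(n);
  std::vector<char> above(n, 0);
  std::vector<double> last_act(n, -1e30);
  std::vector<int> n_act(n, 0);
  std::vector<int> act_node, rep_node;
  std::vector<double> act_time, rep_time;
  std::vector<char> is_stim(n, 0);
  for (int k = 0; k < stim_nodes.size(); ++k) is_stim[stim_nodes[k]] = 1;

  const int n_steps = (int)std::ceil(t_max / dt);
  bool reentry = false;
  double end_time = t_max;
  std::string reason = "time_limit";

  for (int step = 0; step < n_steps; ++step) {
    const double t = step * dt;
    const bool stim_on = (t >= stim_start) && (t < stim_start + stim_duration);
    // reaction
    for (int i = 0; i < n; ++i) {
      double istim = (stim_on && is_stim[i]) ? stim_amplitude : 0.0;
      srl2_step(u[i], v[i], w[i], s[i], b, dt, istim);
    }
    // diffusion: rhs = B u ; solve A x = rhs through the permuted factor
    csc_mult(Bp, Bi, Bx, u, rhs);
    for (int i = 0; i < n; ++i) tmp[i] = rhs[perm[i]];
    csc_lsolve(Lp, Li, Lx, tmp);
    csc_ltsolve(Lp, Li, Lx, tmp);
    for (int i = 0; i < n; ++i) u[perm[i]] = tmp[i];

    const double t1 = (step + 1) * dt;
    if (!R_finite(u[0])) stop("non-finite state at step %d", step + 1);
    // threshold crossings
    for (int i = 0; i < n; ++i) {
      if (!above[i] && u[i] >= threshold) {
        if (t1 - last_act[i] >= lockout_ms) {
          act_node.push_back(i); act_time.push_back(t1);
          last_act[i] = t1; n_act[i]++;
          if (boundary[i] && n_act[i] >= 2) reentry = true;
        }
        above[i] = 1;
      } else if (above[i] && u[i] < threshold) {
        rep_node.push_back(i); rep_time.push_back(t1);
        above[i] = 0;
      }
    }
    if (reentry && stop_on_reentry) {
      end_time = t1; reason = "reentry_stop";
      break;
    }
    if ((step + 1) % check_every == 0 && t1 > stim_start + stim_duration) {
      double umax = 0.0;
      for (int i = 0; i < n; ++i) if (u[i] > umax) umax = u[i];
      if (umax < quiescence_u) { end_time = t1; reason = "quiescence"; break; }
    }
    if (step == n_steps - 1) end_time = t1;
  }

  return List::create(
    _["act_node"] = wrap(act_node),  _["act_time"] = wrap(act_time),
    _["rep_node"] = wrap(rep_node),  _["rep_time"] = wrap(rep_time),
    _["end_time"] = end_time, _["termination"] = reason,
    _["reentry"] = reentry,
    _["u_final"] = wrap(u));
}
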