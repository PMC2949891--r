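// Core numerical kernels: rate-law evaluation for the three GRN formalisms,
// an adaptive Dormand-Prince 4(5) integrator sampling on a fixed output grid,
// and batch objective evaluation for the evolutionary algorithm (node-level
// Eq-9-style and network-level Eq-10-style sum-of-squares fits).
//
// Flat parameter layout ("theta_full"), shared with the R side:
//   ANN   : [v(1..n), theta(1..n), k(1..n), w (n x n, column-major)]
//   SS    : [alpha(1..n), beta(1..n), g (n x n, col-major), h (n x n, col-major)]
//   GRLOT : [v(1..n), k(1..n), n_reg(1..R), K_reg(1..R)] with regulator
//           descriptors (target, source, role) passed separately; regulators
//           ordered by target gene then source gene.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double SS_CLAMP = 1e-12;

struct GrlotDesc {
  const int* target;   // 1-based gene index
  const int* source;   // 1-based gene index
  const double* role;  // +1 activator, -1 inhibitor
  int nreg;
};

// Logistic sigmoid: the single swappable transfer function of the ANN law.
static inline double sigmoid(double x) {
  if (x >= 0) return 1.0 / (1.0 + std::exp(-x));
  double e = std::exp(x);
  return e / (1.0 + e);
}

// Hill-type factors. r = (x/K)^n computed against clamped non-negative x.
static inline double grlot_act(double x, double n, double K) {
  if (x < 0) x = 0;
  double r = std::pow(x / K, n);
  if (!std::isfinite(r)) return (r > 0) ? 1.0 : 0.0;
  return r / (1.0 + r);
}
static inline double grlot_inh(double x, double n, double K) {
  if (x < 0) x = 0;
  double r = std::pow(x / K, n);
  if (!std::isfinite(r)) return (r > 0) ? 0.0 : 1.0;
  return 1.0 / (1.0 + r);
}

// Full-network right-hand side. Returns false on an S-system singularity
// (non-positive concentration raised to a negative kinetic order).
static bool rhs_full(int method, int n, const double* th, const GrlotDesc& gd,
                     const double* x, double* dxdt) {
  if (method == 1) {                       // ANN
    const double* v = th;
    const double* theta = th + n;
    const double* k = th + 2 * n;
    const double* w = th + 3 * n;          // w[i + n*j] = w_ij
    for (int i = 0; i < n; ++i) {
      double s = -theta[i];
      for (int j = 0; j < n; ++j) s += w[i + n * j] * x[j];
      dxdt[i] = v[i] * sigmoid(s) - k[i] * x[i];
    }
  } else if (method == 2) {                // S-system
    const double* alpha = th;
    const double* beta = th + n;
    const double* g = th + 2 * n;
    const double* h = th + 2 * n + n * n;
    bool ok = true;
    for (int i = 0; i < n; ++i) {
      double prod_g = 1.0, prod_h = 1.0;
      for (int j = 0; j < n; ++j) {
        double gij = g[i + n * j], hij = h[i + n * j];
        if (gij != 0.0) {
          if (x[j] <= 0.0 && gij < 0.0) ok = false;
          prod_g *= std::pow(std::max(x[j], SS_CLAMP), gij);
        }
        if (hij != 0.0) {
          if (x[j] <= 0.0 && hij < 0.0) ok = false;
          prod_h *= std::pow(std::max(x[j], SS_CLAMP), hij);
        }
      }
      dxdt[i] = alpha[i] * prod_g - beta[i] * prod_h;
    }
    if (!ok) return false;
  } else {                                 // GRLOT
    const double* v = th;
    const double* k = th + n;
    const double* nr = th + 2 * n;
    const double* Kr = th + 2 * n + gd.nreg;
    for (int i = 0; i < n; ++i) dxdt[i] = v[i];
    for (int r = 0; r < gd.nreg; ++r) {
      int tg = gd.target[r] - 1, sc = gd.source[r] - 1;
      double f = (gd.role[r] > 0) ? grlot_act(x[sc], nr[r], Kr[r])
                                  : grlot_inh(x[sc], nr[r], Kr[r]);
      dxdt[tg] *= f;
    }
    for (int i = 0; i < n; ++i) dxdt[i] -= k[i] * x[i];
  }
  return true;
}

// Node-model right-hand side for gene `node` (0-based): the other genes'
// concentrations are linearly interpolated from the observed trajectory.
struct NodeData {
  const double* times;  // length p
  const double* Y;      // p x n, column-major
  int p, n;
};

static void interp_state(const NodeData& nd, double t, double* x) {
  int p = nd.p;
  if (t <= nd.times[0]) {
    for (int j = 0; j < nd.n; ++j) x[j] = nd.Y[0 + p * j];
    return;
  }
  if (t >= nd.times[p - 1]) {
    for (int j = 0; j < nd.n; ++j) x[j] = nd.Y[(p - 1) + p * j];
    return;
  }
  int lo = 0, hi = p - 1;
  while (hi - lo > 1) {
    int mid = (lo + hi) / 2;
    if (nd.times[mid] <= t) lo = mid; else hi = mid;
  }
  double u = (t - nd.times[lo]) / (nd.times[hi] - nd.times[lo]);
  for (int j = 0; j < nd.n; ++j)
    x[j] = (1 - u) * nd.Y[lo + p * j] + u * nd.Y[hi + p * j];
}

// Single-gene rate evaluation (node models): computes only gene `node`'s
// rate from the full state vector.
static bool rhs_one(int method, int n, const double* th, const GrlotDesc& gd,
                    int i, const double* x, double* dxdt) {
  if (method == 1) {
    const double* v = th;
    const double* theta = th + n;
    const double* k = th + 2 * n;
    const double* w = th + 3 * n;
    double s = -theta[i];
    for (int j = 0; j < n; ++j) s += w[i + n * j] * x[j];
    *dxdt = v[i] * sigmoid(s) - k[i] * x[i];
  } else if (method == 2) {
    const double* alpha = th;
    const double* beta = th + n;
    const double* g = th + 2 * n;
    const double* h = th + 2 * n + n * n;
    bool ok = true;
    double prod_g = 1.0, prod_h = 1.0;
    for (int j = 0; j < n; ++j) {
      double gij = g[i + n * j], hij = h[i + n * j];
      if (gij != 0.0) {
        if (x[j] <= 0.0 && gij < 0.0) ok = false;
        prod_g *= std::pow(std::max(x[j], SS_CLAMP), gij);
      }
      if (hij != 0.0) {
        if (x[j] <= 0.0 && hij < 0.0) ok = false;
        prod_h *= std::pow(std::max(x[j], SS_CLAMP), hij);
      }
    }
    *dxdt = alpha[i] * prod_g - beta[i] * prod_h;
    if (!ok) return false;
  } else {
    const double* v = th;
    const double* k = th + n;
    const double* nr = th + 2 * n;
    const double* Kr = th + 2 * n + gd.nreg;
    double prod = v[i];
    for (int r = 0; r < gd.nreg; ++r) {
      if (gd.target[r] - 1 != i) continue;
      int sc = gd.source[r] - 1;
      prod *= (gd.role[r] > 0) ? grlot_act(x[sc], nr[r], Kr[r])
                               : grlot_inh(x[sc], nr[r], Kr[r]);
    }
    *dxdt = prod - k[i] * x[i];
  }
  return true;
}

static bool rhs_node(int method, int n, const double* th, const GrlotDesc& gd,
                     int node, const NodeData& nd, double t, double xk,
                     double* dxkdt, double* xbuf) {
  interp_state(nd, t, xbuf);
  xbuf[node] = xk;
  return rhs_one(method, n, th, gd, node, xbuf, dxkdt);
}

// Dormand-Prince 4(5) coefficients.
static const double DP_c[7] = {0.0, 1.0 / 5, 3.0 / 10, 4.0 / 5, 8.0 / 9, 1.0, 1.0};
static const double DP_a[7][6] = {
  {0, 0, 0, 0, 0, 0},
  {1.0 / 5, 0, 0, 0, 0, 0},
  {3.0 / 40, 9.0 / 40, 0, 0, 0, 0},
  {44.0 / 45, -56.0 / 15, 32.0 / 9, 0, 0, 0},
  {19372.0 / 6561, -25360.0 / 2187, 64448.0 / 6561, -212.0 / 729, 0, 0},
  {9017.0 / 3168, -355.0 / 33, 46732.0 / 5247, 49.0 / 176, -5103.0 / 18656, 0},
  {35.0 / 384, 0, 500.0 / 1113, 125.0 / 192, -2187.0 / 6784, 11.0 / 84}};
static const double DP_b5[7] = {35.0 / 384, 0, 500.0 / 1113, 125.0 / 192,
                                -2187.0 / 6784, 11.0 / 84, 0};
static const double DP_b4[7] = {5179.0 / 57600, 0, 7571.0 / 16695, 393.0 / 640,
                                -92097.0 / 339200, 187.0 / 2100, 1.0 / 40};

struct OdeProblem {
  int method, n;
  const double* th;
  GrlotDesc gd;
  bool node_mode;
  int node;
  NodeData nd;
  std::vector<double> xbuf, dbuf;

  int dim() const { return node_mode ? 1 : n; }
  bool deriv(double t, const double* y, double* dy) {
    if (node_mode)
      return rhs_node(method, n, th, gd, node, nd, t, y[0], dy, xbuf.data());
    return rhs_full(method, n, th, gd, y, dy);
  }
};

// Integrate over the output grid `times`, writing states into `out`
// (p x dim, column-major).  Returns the number of grid rows successfully
// filled (== p on success); unfilled rows are set to `blowup`.
static int dopri5_grid(OdeProblem& pr, const double* x0, const double* times,
                       int p, double rtol, double atol, double blowup,
                       double* out, long max_steps = 200000) {
  int d = pr.dim();
  std::vector<double> y(x0, x0 + d), k(7 * d), ytmp(d), y5(d), y4(d);
  double t = times[0];
  for (int j = 0; j < d; ++j) out[0 + p * j] = y[j];
  double span = times[p - 1] - times[0];
  double h = span / 100.0, hmin = span * 1e-13;
  long steps = 0;
  int filled = 1;
  bool have_k1 = false;

  for (int row = 1; row < p; ++row) {
    double t_target = times[row];
    while (t < t_target) {
      if (++steps > max_steps) goto fail;
      bool hit = false;
      double hstep = h;
      if (t + hstep >= t_target) { hstep = t_target - t; hit = true; }
      if (!have_k1) {
        if (!pr.deriv(t, y.data(), &k[0])) goto fail;
        have_k1 = true;
      }
      bool stage_ok = true;
      for (int s = 1; s < 7; ++s) {
        for (int j = 0; j < d; ++j) {
          double acc = y[j];
          for (int q = 0; q < s; ++q) acc += hstep * DP_a[s][q] * k[q * d + j];
          ytmp[j] = acc;
        }
        if (!pr.deriv(t + DP_c[s] * hstep, ytmp.data(), &k[s * d])) {
          stage_ok = false;
          break;
        }
      }
      if (!stage_ok) goto fail;
      double errnorm = 0.0;
      bool finite = true;
      for (int j = 0; j < d; ++j) {
        double s5 = y[j], s4 = y[j];
        for (int s = 0; s < 7; ++s) {
          s5 += hstep * DP_b5[s] * k[s * d + j];
          s4 += hstep * DP_b4[s] * k[s * d + j];
        }
        y5[j] = s5;
        y4[j] = s4;
        if (!std::isfinite(s5)) { finite = false; break; }
        double sc = atol + rtol * std::max(std::fabs(y[j]), std::fabs(s5));
        double e = (s5 - s4) / sc;
        errnorm += e * e;
      }
      if (!finite) {
        h = hstep / 4.0;
        have_k1 = true;  // k1 at (t, y) still valid
        if (h < hmin) goto fail;
        continue;
      }
      errnorm = std::sqrt(errnorm / d);
      if (errnorm <= 1.0) {
        t = hit ? t_target : t + hstep;
        y = y5;
        // FSAL: the 7th stage was evaluated at (t + h, y5)
        for (int j = 0; j < d; ++j) k[j] = k[6 * d + j];
        have_k1 = true;
        for (int j = 0; j < d; ++j)
          if (std::fabs(y[j]) > blowup) goto fail;
        double fac = (errnorm == 0) ? 5.0
                     : std::min(5.0, std::max(0.2, 0.9 * std::pow(errnorm, -0.2)));
        h = std::min(hstep * fac, span / 4.0);
      } else {
        h = hstep * std::max(0.2, 0.9 * std::pow(errnorm, -0.2));
        have_k1 = true;
        if (h < hmin) goto fail;
      }
    }
    for (int j = 0; j < d; ++j) out[row + p * j] = y[j];
    filled = row + 1;
  }
  return filled;
fail:
  for (int row = filled; row < p; ++row)
    for (int j = 0; j < d; ++j) out[row + p * j] = blowup;
  return filled;
}

static GrlotDesc make_desc(const IntegerVector& tg, const IntegerVector& sc,
                           const NumericVector& role) {
  GrlotDesc gd;
  gd.target = tg.size() ? &tg[0] : NULL;
  gd.source = sc.size() ? &sc[0] : NULL;
  gd.role = role.size() ? &role[0] : NULL;
  gd.nreg = tg.size();
  return gd;
}

// [[Rcpp::export]]
List cpp_integrate(int method, int n, NumericVector theta_full,
                   IntegerVector reg_target, IntegerVector reg_source,
                   NumericVector reg_role, NumericVector x0,
                   NumericVector times, double rtol, double atol,
                   double blowup) {
  int p = times.size();
  OdeProblem pr;
  pr.method = method;
  pr.n = n;
  pr.th = &theta_full[0];
  pr.gd = make_desc(reg_target, reg_source, reg_role);
  pr.node_mode = false;
  pr.node = 0;
  pr.xbuf.resize(n);
  pr.dbuf.resize(n);
  NumericMatrix out(p, n);
  int filled = dopri5_grid(pr, &x0[0], &times[0], p, rtol, atol, blowup,
                           &out(0, 0));
  return List::create(_["states"] = out, _["ok"] = (filled == p),
                      _["filled"] = filled);
}

// [[Rcpp::export]]
List cpp_integrate_node(int method, int n, NumericVector theta_full,
                        IntegerVector reg_target, IntegerVector reg_source,
                        NumericVector reg_role, int node,
                        NumericVector data_times, NumericMatrix data_states,
                        double rtol, double atol, double blowup) {
  int p = data_times.size();
  OdeProblem pr;
  pr.method = method;
  pr.n = n;
  pr.th = &theta_full[0];
  pr.gd = make_desc(reg_target, reg_source, reg_role);
  pr.node_mode = true;
  pr.node = node - 1;
  pr.nd.times = &data_times[0];
  pr.nd.Y = &data_states(0, 0);
  pr.nd.p = p;
  pr.nd.n = n;
  pr.xbuf.resize(n);
  pr.dbuf.resize(n);
  NumericMatrix out(p, 1);
  double x0 = data_states(0, node - 1);
  int filled = dopri5_grid(pr, &x0, &data_times[0], p, rtol, atol, blowup,
                           &out(0, 0));
  return List::create(_["states"] = out, _["ok"] = (filled == p),
                      _["filled"] = filled);
}

// Batch objective for the EA.  `pop` is pop_size x D; each row is scattered
// into a copy of `template_full` at (1-based) positions `idx_free`.
// scope = 0: network fit (SSE over all genes, integrated from each
// trajectory's first row); scope = k > 0: node fit for gene k (SSE over that
// gene only, remaining genes interpolated from the data).  Any integration
// failure maps the individual to `sentinel`.
// [[Rcpp::export]]
NumericVector cpp_batch_objective(NumericMatrix pop, NumericVector template_full,
                                  IntegerVector idx_free, int method, int n,
                                  IntegerVector reg_target,
                                  IntegerVector reg_source,
                                  NumericVector reg_role, int scope,
                                  List traj_times, List traj_states,
                                  double rtol, double atol, double blowup,
                                  double sentinel) {
  int npop = pop.nrow(), D = pop.ncol(), ntraj = traj_times.size();
  NumericVector res(npop);
  std::vector<double> th(template_full.begin(), template_full.end());

  std::vector<NumericVector> tt(ntraj);
  std::vector<NumericMatrix> ts(ntraj);
  for (int r = 0; r < ntraj; ++r) {
    tt[r] = as<NumericVector>(traj_times[r]);
    ts[r] = as<NumericMatrix>(traj_states[r]);
  }

  OdeProblem pr;
  pr.method = method;
  pr.n = n;
  pr.gd = make_desc(reg_target, reg_source, reg_role);
  pr.xbuf.resize(n);
  pr.dbuf.resize(n);

  int d = (scope == 0) ? n : 1;
  for (int i = 0; i < npop; ++i) {
    for (int q = 0; q < D; ++q) th[idx_free[q] - 1] = pop(i, q);
    pr.th = th.data();
    double sse = 0.0;
    bool ok = true;
    for (int r = 0; r < ntraj && ok; ++r) {
      int p = tt[r].size();
      std::vector<double> out(p * d);
      int filled;
      if (scope == 0) {
        pr.node_mode = false;
        std::vector<double> x0(n);
        for (int j = 0; j < n; ++j) x0[j] = ts[r](0, j);
        filled = dopri5_grid(pr, x0.data(), &tt[r][0], p, rtol, atol, blowup,
                             out.data(), 20000);
        if (filled < p) { ok = false; break; }
        for (int j = 0; j < n; ++j)
          for (int t = 0; t < p; ++t) {
            double e = ts[r](t, j) - out[t + p * j];
            sse += e * e;
          }
      } else {
        pr.node_mode = true;
        pr.node = scope - 1;
        pr.nd.times = &tt[r][0];
        pr.nd.Y = &ts[r](0, 0);
        pr.nd.p = p;
        pr.nd.n = n;
        double x0 = ts[r](0, scope - 1);
        filled = dopri5_grid(pr, &x0, &tt[r][0], p, rtol, atol, blowup,
                             out.data(), 20000);
        if (filled < p) { ok = false; break; }
        for (int t = 0; t < p; ++t) {
          double e = ts[r](t, scope - 1) - out[t];
          sse += e * e;
        }
      }
    }
    res[i] = (ok && std::isfinite(sse)) ? sse : sentinel;
  }
  return res;
}
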