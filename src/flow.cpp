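#include <Rcpp.h>
#include <vector>
#include <deque>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Minimum-cost flow by successive shortest paths on the residual network.
// Arcs are stored in pairs (forward at even index, residual reverse at odd),
// so `id ^ 1` is the companion arc. Costs may be negative on input arcs;
// negative arcs are pre-saturated before augmentation so that the starting
// pseudoflow admits no negative residual cycle. Capacities and supplies are
// doubles: the Lagrangian subproblems carry real-valued node supplies, while
// all arc costs stay integral, which keeps shortest-path distances (and hence
// the recovered node potentials and y-values) integral.
struct MCF {
  int n;
  std::vector<std::vector<int> > adj;
  std::vector<int> to;
  std::vector<double> cap, cst;
  std::vector<double> excess;

  explicit MCF(int n_) : n(n_), adj(n_), excess(n_, 0.0) {}

  int add_arc(int u, int v, double c, double w) {
    int id = (int) to.size();
    to.push_back(v); cap.push_back(c); cst.push_back(w); adj[u].push_back(id);
    to.push_back(u); cap.push_back(0.0); cst.push_back(-w); adj[v].push_back(id + 1);
    return id;
  }

  // push flow along every negative-cost arc up to capacity; the induced
  // imbalances are folded into the node excesses and drained later.
  void saturate_negative(double tol) {
    for (int id = 0; id < (int) to.size(); id += 2) {
      if (cst[id] < 0 && cap[id] > tol) {
        double c = cap[id];
        int u = to[id ^ 1], v = to[id];
        cap[id] = 0.0; cap[id ^ 1] += c;
        excess[u] -= c; excess[v] += c;
      }
    }
  }

  // SPFA shortest path: residual costs can be negative on reverse arcs but
  // the no-negative-cycle invariant of successive shortest paths holds.
  bool solve(double tol = 1e-9) {
    const double INF = std::numeric_limits<double>::infinity();
    for (;;) {
      int s = -1;
      for (int i = 0; i < n; ++i) if (excess[i] > tol) { s = i; break; }
      if (s < 0) return true;
      std::vector<double> dist(n, INF);
      std::vector<int> pre(n, -1);
      std::vector<char> inq(n, 0);
      std::deque<int> q;
      dist[s] = 0.0; q.push_back(s); inq[s] = 1;
      while (!q.empty()) {
        int u = q.front(); q.pop_front(); inq[u] = 0;
        for (size_t a = 0; a < adj[u].size(); ++a) {
          int id = adj[u][a];
          if (cap[id] <= tol) continue;
          int v = to[id];
          double nd = dist[u] + cst[id];
          if (nd < dist[v] - 1e-9) {
            dist[v] = nd; pre[v] = id;
            if (!inq[v]) { inq[v] = 1; q.push_back(v); }
          }
        }
      }
      int t = -1; double bd = INF;
      for (int i = 0; i < n; ++i)
        if (excess[i] < -tol && dist[i] < bd - 1e-9) { bd = dist[i]; t = i; }
      if (t < 0) {
        // residual imbalances below rounding dust are numeric noise from
        // real-valued supplies, not infeasibility
        double mx = 0.0;
        for (int i = 0; i < n; ++i) mx = std::max(mx, excess[i]);
        return mx <= 1e-6;
      }
      double delta = std::min(excess[s], -excess[t]);
      for (int v = t; v != s;) { int id = pre[v]; if (id < 0) return false;
        delta = std::min(delta, cap[id]); v = to[id ^ 1]; }
      for (int v = t; v != s;) { int id = pre[v];
        cap[id] -= delta; cap[id ^ 1] += delta; v = to[id ^ 1]; }
      excess[s] -= delta; excess[t] += delta;
    }
  }

  double flow_on(int id) const { return cap[id ^ 1]; }

  double total_cost() const {
    double c = 0.0;
    for (int id = 0; id < (int) to.size(); id += 2) c += cst[id] * cap[id ^ 1];
    return c;
  }

  // Bellman-Ford distances from a virtual source connected to every node by a
  // zero-cost arc; on an optimal residual network these are valid (and
  // deterministic) node potentials.
  std::vector<double> potentials(double tol = 1e-9) const {
    std::vector<double> d(n, 0.0);
    for (int it = 0; it < n; ++it) {
      bool ch = false;
      for (int u = 0; u < n; ++u)
        for (size_t a = 0; a < adj[u].size(); ++a) {
          int id = adj[u][a];
          if (cap[id] <= tol) continue;
          if (d[u] + cst[id] < d[to[id]] - 1e-9) { d[to[id]] = d[u] + cst[id]; ch = true; }
        }
      if (!ch) break;
    }
    return d;
  }
};

// Fragment-graph LP over m parts in part-position coordinates.
// Network: nodes 0..m (node p-1 and p flank part p). Per part p:
//   arc (p-1 -> p), cost 0, cap Inf  and  arc (p -> p-1), cost cap_p, cap Inf
// encode 0 <= y_p <= cap_p. Per fragment spanning parts i..j:
//   arc (j -> i-1), cost b_f, cap 1  and  arc (i-1 -> j), cost -bbar_f, cap 1
// charge unit error above b_f / below bbar_f. Node supplies are the
// differenced multipliers (0 for the pure circulation of the 2-color LP).
// The circulation solves the DUAL of the interval LP; primal y-values are
// differences of neighboring node potentials.
struct FragLP {
  int m, Fn;
  double lp_value;           // optimal value of the primal interval LP
  std::vector<double> y;     // optimal integral y per part
  bool ok;
};

static FragLP frag_lp(const std::vector<double>& caps,
                      const std::vector<int>& fi, const std::vector<int>& fj,
                      const std::vector<double>& bup, const std::vector<double>& blo,
                      const std::vector<double>& lambda) {
  const double BIG = 1e15;
  int m = (int) caps.size(), Fn = (int) fi.size();
  FragLP out; out.m = m; out.Fn = Fn; out.ok = true;
  if (m == 0) { out.lp_value = 0.0; return out; }
  MCF net(m + 1);
  for (int p = 0; p < m; ++p) {
    net.add_arc(p, p + 1, BIG, 0.0);
    net.add_arc(p + 1, p, BIG, caps[p]);
  }
  for (int f = 0; f < Fn; ++f) {
    net.add_arc(fj[f], fi[f] - 1, 1.0, bup[f]);
    net.add_arc(fi[f] - 1, fj[f], 1.0, -blo[f]);
  }
  if (!lambda.empty()) {
    net.excess[0] += lambda[0];
    for (int p = 1; p < m; ++p) net.excess[p] += lambda[p] - lambda[p - 1];
    net.excess[m] -= lambda[m - 1];
  }
  net.saturate_negative(1e-9);
  if (!net.solve()) {
    out.ok = false; out.lp_value = R_PosInf;
    out.y.assign(m, 0.0);
    return out;
  }
  out.lp_value = -net.total_cost();
  std::vector<double> pot = net.potentials();
  out.y.resize(m);
  for (int p = 0; p < m; ++p) {
    double v = pot[p] - pot[p + 1];
    if (v < 0) v = 0;
    if (v > caps[p]) v = caps[p];
    out.y[p] = v;
  }
  return out;
}

// [[Rcpp::export(name = ".frag_lp_cpp")]]
List frag_lp_cpp(NumericVector caps, IntegerVector fi, IntegerVector fj,
                 NumericVector bup, NumericVector blo, NumericVector lambda) {
  std::vector<double> c(caps.begin(), caps.end());
  std::vector<int> i1(fi.begin(), fi.end()), j1(fj.begin(), fj.end());
  std::vector<double> bu(bup.begin(), bup.end()), bl(blo.begin(), blo.end());
  std::vector<double> lam(lambda.begin(), lambda.end());
  FragLP r = frag_lp(c, i1, j1, bu, bl, lam);
  return List::create(_["value"] = r.lp_value,
                      _["y"] = NumericVector(r.y.begin(), r.y.end()),
                      _["feasible"] = r.ok);
}

// Per-color Lagrangian subproblem inside box bounds [lo, hi]:
//   min sum_f |a_f' y - b_f| + lambda' y   s.t.  lo <= y <= hi, y integral.
// Substituting y = lo + y' reduces to the standard fragment LP with shifted
// requirements; total unimodularity makes the potential-recovered y integral.
static double lag_sub(const std::vector<int>& fi, const std::vector<int>& fj,
                      const std::vector<double>& bk, const std::vector<double>& lam,
                      const std::vector<double>& lo, const std::vector<double>& hi,
                      std::vector<double>& y_out) {
  int m = (int) lo.size(), Fn = (int) fi.size();
  std::vector<double> caps(m), bshift(Fn);
  for (int p = 0; p < m; ++p) caps[p] = hi[p] - lo[p];
  for (int f = 0; f < Fn; ++f) {
    double s = bk[f];
    for (int p = fi[f] - 1; p <= fj[f] - 1; ++p) s -= lo[p];
    bshift[f] = s;
  }
  FragLP r = frag_lp(caps, fi, fj, bshift, bshift, lam);
  y_out.resize(m);
  double val = 0.0;
  for (int p = 0; p < m; ++p) { y_out[p] = lo[p] + r.y[p]; val += lam[p] * y_out[p]; }
  for (int f = 0; f < Fn; ++f) {
    double s = -bk[f];
    for (int p = fi[f] - 1; p <= fj[f] - 1; ++p) s += y_out[p];
    val += std::fabs(s);
  }
  return val;
}

// [[Rcpp::export(name = ".lag_subproblem_cpp")]]
List lag_subproblem_cpp(IntegerVector fi, IntegerVector fj, NumericVector bk,
                        NumericVector lambda, NumericVector lo, NumericVector hi) {
  std::vector<int> i1(fi.begin(), fi.end()), j1(fj.begin(), fj.end());
  std::vector<double> b(bk.begin(), bk.end()), lam(lambda.begin(), lambda.end());
  std::vector<double> l(lo.begin(), lo.end()), h(hi.begin(), hi.end());
  std::vector<double> y;
  double v = lag_sub(i1, j1, b, lam, l, h, y);
  return List::create(_["y"] = NumericVector(y.begin(), y.end()), _["value"] = v);
}

// Held-Karp subgradient loop for the Lagrangian dual, run entirely in C++.
// Returns the best bound, the multipliers attaining it, the window-average of
// the subproblem solutions over the last `h` iterations (used for branching),
// and, when the subgradient vanishes, the feasible optimal y it certifies.
// [[Rcpp::export(name = ".lag_subgradient_cpp")]]
List lag_subgradient_cpp(NumericVector P, IntegerVector fi, IntegerVector fj,
                         NumericMatrix b, NumericMatrix lo, NumericMatrix hi,
                         NumericVector lambda0, double UB,
                         double theta0, int halve_after, double theta_min,
                         int iter_cap, double prune_above, int h) {
  int m = P.size(), Fn = fi.size(), K = b.ncol();
  std::vector<int> i1(fi.begin(), fi.end()), j1(fj.begin(), fj.end());
  std::vector<double> lam(lambda0.begin(), lambda0.end());
  std::vector<double> best_lam(lam);
  double best = R_NegInf, theta = theta0;
  int stall = 0, iter = 0;
  bool zero_sub = false;
  std::deque<std::vector<double> > window;  // flattened m*K solutions
  std::vector<double> y_feas;
  double feas_err = R_PosInf;

  std::vector<std::vector<double> > bk(K), lok(K), hik(K);
  for (int k = 0; k < K; ++k) {
    bk[k].resize(Fn); lok[k].resize(m); hik[k].resize(m);
    for (int f = 0; f < Fn; ++f) bk[k][f] = b(f, k);
    for (int p = 0; p < m; ++p) { lok[k][p] = lo(p, k); hik[k][p] = hi(p, k); }
  }

  while (iter < iter_cap && theta >= theta_min) {
    ++iter;
    double z = 0.0;
    std::vector<double> flat(m * K);
    std::vector<double> g(m, 0.0);
    for (int k = 0; k < K; ++k) {
      std::vector<double> yk;
      z += lag_sub(i1, j1, bk[k], lam, lok[k], hik[k], yk);
      for (int p = 0; p < m; ++p) { flat[p + k * m] = yk[p]; g[p] += yk[p]; }
    }
    for (int p = 0; p < m; ++p) { z -= lam[p] * P[p]; g[p] -= P[p]; }
    window.push_back(flat);
    if ((int) window.size() > h) window.pop_front();
    if (z > best + 1e-9) { best = z; best_lam = lam; stall = 0; }
    else if (++stall >= halve_after) { theta *= 0.5; stall = 0; }
    double gn2 = 0.0;
    for (int p = 0; p < m; ++p) gn2 += g[p] * g[p];
    if (gn2 <= 1e-18) {
      // relaxation solution satisfies the linking constraints: z equals the
      // true error of this y, so it is optimal within the box
      zero_sub = true;
      y_feas = flat;
      feas_err = z;
      break;
    }
    if (best > prune_above + 1e-9) break;     // bound already proves a prune
    if (UB - z <= 0) { if (best >= UB - 1e-9) break; }
    double mu = theta * (UB - z) / gn2;
    if (mu > 0)
      for (int p = 0; p < m; ++p) lam[p] += mu * g[p];
  }

  NumericMatrix ybar(m, K);
  if (!window.empty()) {
    for (size_t w = 0; w < window.size(); ++w)
      for (int p = 0; p < m; ++p)
        for (int k = 0; k < K; ++k) ybar(p, k) += window[w][p + k * m];
    for (int p = 0; p < m; ++p)
      for (int k = 0; k < K; ++k) ybar(p, k) /= (double) window.size();
  }
  List out = List::create(_["best_bound"] = best,
                          _["best_lambda"] = NumericVector(best_lam.begin(), best_lam.end()),
                          _["ybar"] = ybar,
                          _["zero_subgradient"] = zero_sub,
                          _["iterations"] = iter,
                          _["theta_final"] = theta);
  if (zero_sub) {
    NumericMatrix yf(m, K);
    for (int p = 0; p < m; ++p)
      for (int k = 0; k < K; ++k) yf(p, k) = y_feas[p + k * m];
    out["y_feasible"] = yf;
    out["feasible_error"] = feas_err;
  }
  return out;
}
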