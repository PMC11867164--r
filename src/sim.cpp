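#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Event-driven simulators for linear birth-death processes and the
// regression-tree builder behind the ABC forests. All randomness comes
// from R's RNG, so set.seed() on the R side governs reproducibility.

namespace {

struct TreeBuf {
  std::vector<int> parent;      // 0-based parent index, -1 for a root
  std::vector<double> birth;
  std::vector<double> end;
  std::vector<int> reason;      // 1 split, 2 death, 3 observed
};

// Simulate a complete linear BDP tree from z0 founder lineages at time 0.
// Stops at t_max (if finite), when the number of extant lineages first
// reaches n_max (if n_max > 0), or at extinction. Returns true if any
// lineage is extant at the stopping time.
bool sim_core(double lambda, double mu, double t_max, int n_max, int z0,
              TreeBuf &tb, double &t_final) {
  tb.parent.clear(); tb.birth.clear(); tb.end.clear(); tb.reason.clear();
  std::vector<int> alive;
  alive.reserve(n_max > 0 ? n_max : 64);
  for (int i = 0; i < z0; ++i) {
    tb.parent.push_back(-1); tb.birth.push_back(0.0);
    tb.end.push_back(NA_REAL); tb.reason.push_back(0);
    alive.push_back(i);
  }
  double t = 0.0;
  const double rate = lambda + mu;
  const double psplit = lambda / rate;
  if (n_max > 0 && (int)alive.size() >= n_max) {
    for (size_t i = 0; i < alive.size(); ++i) {
      tb.end[alive[i]] = 0.0; tb.reason[alive[i]] = 3;
    }
    t_final = 0.0;
    return true;
  }
  for (;;) {
    int n = (int)alive.size();
    if (n == 0) { t_final = t; return false; }
    double dt = R::exp_rand() / (n * rate);
    if (R_FINITE(t_max) && t + dt > t_max) {
      for (int i = 0; i < n; ++i) {
        tb.end[alive[i]] = t_max; tb.reason[alive[i]] = 3;
      }
      t_final = t_max;
      return true;
    }
    t += dt;
    int k = (int)(R::unif_rand() * n); if (k >= n) k = n - 1;
    int id = alive[k];
    if (R::unif_rand() < psplit) {
      tb.end[id] = t; tb.reason[id] = 1;
      int c1 = (int)tb.parent.size();
      tb.parent.push_back(id); tb.birth.push_back(t);
      tb.end.push_back(NA_REAL); tb.reason.push_back(0);
      tb.parent.push_back(id); tb.birth.push_back(t);
      tb.end.push_back(NA_REAL); tb.reason.push_back(0);
      alive[k] = c1;
      alive.push_back(c1 + 1);
      if (n_max > 0 && (int)alive.size() >= n_max) {
        for (size_t i = 0; i < alive.size(); ++i) {
          tb.end[alive[i]] = t; tb.reason[alive[i]] = 3;
        }
        t_final = t;
        return true;
      }
    } else {
      tb.end[id] = t; tb.reason[id] = 2;
      alive[k] = alive.back();
      alive.pop_back();
    }
  }
}

List tree_to_list(const TreeBuf &tb, double t_final, bool extant) {
  int n = (int)tb.parent.size();
  IntegerVector parent(n), reason(n);
  NumericVector birth(n), end(n);
  for (int i = 0; i < n; ++i) {
    parent[i] = tb.parent[i] < 0 ? NA_INTEGER : tb.parent[i] + 1;
    birth[i] = tb.birth[i];
    end[i] = tb.end[i];
    reason[i] = tb.reason[i];
  }
  return List::create(_["parent"] = parent, _["birth"] = birth,
                      _["end"] = end, _["reason"] = reason,
                      _["t_final"] = t_final, _["extant"] = extant);
}

} // namespace

// [[Rcpp::export]]
List cpp_sim_bd_tree(double lambda, double mu, double t_max, int z0) {
  TreeBuf tb;
  double t_final;
  bool extant = sim_core(lambda, mu, t_max, 0, z0, tb, t_final);
  return tree_to_list(tb, t_final, extant);
}

// Grow a population from one founder until n_target concurrent lineages,
// restarting on extinction (up to max_attempts).
// [[Rcpp::export]]
List cpp_grow_to_n(double lambda, double mu, int n_target, int max_attempts) {
  TreeBuf tb;
  double t_final = 0.0;
  for (int a = 1; a <= max_attempts; ++a) {
    bool ok = sim_core(lambda, mu, R_PosInf, n_target, 1, tb, t_final);
    if (ok) {
      List out = tree_to_list(tb, t_final, true);
      out["attempts"] = a;
      return out;
    }
  }
  return List::create(_["attempts"] = max_attempts, _["failed"] = true);
}

// Final population sizes of reps independent LBDPs run to time t.
// [[Rcpp::export]]
IntegerVector cpp_bd_final_sizes(double lambda, double mu, double t,
                                 int z0, int reps) {
  IntegerVector out(reps);
  const double rate = lambda + mu;
  const double psplit = lambda / rate;
  for (int r = 0; r < reps; ++r) {
    int n = z0;
    double tt = 0.0;
    while (n > 0) {
      double dt = R::exp_rand() / (n * rate);
      if (tt + dt > t) break;
      tt += dt;
      if (R::unif_rand() < psplit) ++n; else --n;
    }
    out[r] = n;
  }
  return out;
}

// Final sizes for a time-inhomogeneous pure-birth process simulated by
// thinning with a constant majorant rate_max >= rate(u) on [0, t].
// rate_fn is evaluated in R; used as an independent test oracle.
// [[Rcpp::export]]
IntegerVector cpp_inhom_yule_sizes(Function rate_fn, double rate_max,
                                   double t, int reps) {
  IntegerVector out(reps);
  for (int r = 0; r < reps; ++r) {
    int n = 1;
    double tt = 0.0;
    for (;;) {
      double dt = R::exp_rand() / (n * rate_max);
      if (tt + dt > t) break;
      tt += dt;
      double lam = as<double>(rate_fn(tt));
      if (R::unif_rand() < lam / rate_max) ++n;
    }
    out[r] = n;
  }
  return out;
}

// Family sizes at time t under Poisson(theta) immigration with LBDP
// family growth; one IntegerVector of sizes (extinct families are 0)
// per replicate.
// [[Rcpp::export]]
List cpp_family_sizes_reps(double theta, double lambda, double mu,
                           double t, int reps) {
  List out(reps);
  const double rate = lambda + mu;
  const double psplit = lambda / rate;
  for (int r = 0; r < reps; ++r) {
    int k = (int)R::rpois(theta * t);
    IntegerVector sizes(k);
    for (int j = 0; j < k; ++j) {
      double u = R::unif_rand() * t;  // arrival time
      int n = 1;
      double tt = u;
      while (n > 0) {
        double dt = R::exp_rand() / (n * rate);
        if (tt + dt > t) break;
        tt += dt;
        if (R::unif_rand() < psplit) ++n; else --n;
      }
      sizes[j] = n;
    }
    out[r] = sizes;
  }
  return out;
}

// Yule-with-immigration window counts. Each window is a row (lo, hi) of
// `windows`; modes[w] == 0 counts families with any appearance (arrival
// or birth) in (lo, hi]; modes[w] == 1 counts families arriving in
// (0, lo] with at least one birth (offspring) in (lo, hi].
// [[Rcpp::export]]
IntegerMatrix cpp_yule_imm_window_counts(double theta, double lambda,
                                         double t_end,
                                         NumericMatrix windows,
                                         IntegerVector modes, int reps) {
  int W = windows.nrow();
  IntegerMatrix out(reps, W);
  for (int r = 0; r < reps; ++r) {
    int K = (int)R::rpois(theta * t_end);
    for (int f = 0; f < K; ++f) {
      double u = R::unif_rand() * t_end;     // arrival
      std::vector<bool> hit(W, false);
      for (int w = 0; w < W; ++w) {
        if (modes[w] == 0 && u > windows(w, 0) && u <= windows(w, 1))
          hit[w] = true;
      }
      int n = 1;
      double tt = u;
      for (;;) {
        double dt = R::exp_rand() / (n * lambda);
        if (tt + dt > t_end) break;
        tt += dt;
        ++n;
        for (int w = 0; w < W; ++w) {
          if (hit[w]) continue;
          if (tt > windows(w, 0) && tt <= windows(w, 1)) {
            if (modes[w] == 0 || u <= windows(w, 0)) hit[w] = true;
          }
        }
      }
      for (int w = 0; w < W; ++w) if (hit[w]) ++out(r, w);
    }
  }
  return out;
}

// ---------------------------------------------------------------------
// Regression tree with feature-subsampled, variance-reduction splits on
// a (possibly multivariate) standardized response. Used by bd_forest().

namespace {

struct NodeTask { int id, lo, hi; };

// partial Fisher-Yates draw of mtry distinct feature indices
void draw_features(int d, int mtry, std::vector<int> &feat) {
  feat.resize(d);
  for (int i = 0; i < d; ++i) feat[i] = i;
  for (int i = 0; i < mtry; ++i) {
    int j = i + (int)(R::unif_rand() * (d - i));
    if (j >= d) j = d - 1;
    std::swap(feat[i], feat[j]);
  }
  feat.resize(mtry);
}

} // namespace

// [[Rcpp::export]]
List cpp_build_tree(NumericMatrix X, NumericMatrix Y, IntegerVector rows,
                    int mtry, int min_leaf) {
  const int d = X.ncol(), q = Y.ncol();
  const int ntot = rows.size();
  std::vector<int> idx(rows.begin(), rows.end());   // 0-based, multiplicity
  std::vector<int> split_var, left, right;
  std::vector<double> split_val;
  std::vector<NodeTask> stack;

  split_var.push_back(-1); split_val.push_back(0.0);
  left.push_back(-1); right.push_back(-1);
  stack.push_back({0, 0, ntot});

  std::vector<int> feat;
  std::vector<std::pair<double, int> > xr;
  std::vector<double> pre((size_t)q, 0.0);

  while (!stack.empty()) {
    NodeTask nd = stack.back(); stack.pop_back();
    int n = nd.hi - nd.lo;
    if (n <= min_leaf) continue;                    // stays a leaf

    // response totals and constancy check
    std::vector<double> S(q, 0.0);
    bool yconst = true;
    for (int i = nd.lo; i < nd.hi; ++i)
      for (int c = 0; c < q; ++c) S[c] += Y(idx[i], c);
    for (int i = nd.lo + 1; i < nd.hi && yconst; ++i)
      for (int c = 0; c < q; ++c)
        if (Y(idx[i], c) != Y(idx[nd.lo], c)) { yconst = false; break; }
    if (yconst) continue;

    draw_features(d, mtry, feat);
    double base = 0.0;
    for (int c = 0; c < q; ++c) base += S[c] * S[c] / n;
    double best_gain = base;
    int best_f = -1; double best_thr = 0.0;

    for (size_t fi = 0; fi < feat.size(); ++fi) {
      int f = feat[fi];
      xr.resize(n);
      for (int i = 0; i < n; ++i)
        xr[i] = std::make_pair(X(idx[nd.lo + i], f), idx[nd.lo + i]);
      std::sort(xr.begin(), xr.end());
      if (xr[0].first == xr[n - 1].first) continue;
      std::vector<double> SL(q, 0.0);
      for (int i = 1; i < n; ++i) {
        for (int c = 0; c < q; ++c) SL[c] += Y(xr[i - 1].second, c);
        if (xr[i - 1].first == xr[i].first) continue;
        double gain = 0.0;
        for (int c = 0; c < q; ++c) {
          double sl = SL[c], sr = S[c] - sl;
          gain += sl * sl / i + sr * sr / (n - i);
        }
        if (gain > best_gain + 1e-12) {
          best_gain = gain; best_f = f;
          best_thr = 0.5 * (xr[i - 1].first + xr[i].first);
        }
      }
    }
    if (best_f < 0) continue;

    // stable partition of idx[lo, hi) on x <= thr
    std::vector<int> lo_part, hi_part;
    lo_part.reserve(n); hi_part.reserve(n);
    for (int i = nd.lo; i < nd.hi; ++i) {
      if (X(idx[i], best_f) <= best_thr) lo_part.push_back(idx[i]);
      else hi_part.push_back(idx[i]);
    }
    int nL = (int)lo_part.size();
    if (nL == 0 || nL == n) continue;               // numerical guard
    std::copy(lo_part.begin(), lo_part.end(), idx.begin() + nd.lo);
    std::copy(hi_part.begin(), hi_part.end(), idx.begin() + nd.lo + nL);

    int lid = (int)split_var.size();
    split_var.push_back(-1); split_val.push_back(0.0);
    left.push_back(-1); right.push_back(-1);
    int rid = (int)split_var.size();
    split_var.push_back(-1); split_val.push_back(0.0);
    left.push_back(-1); right.push_back(-1);
    split_var[nd.id] = best_f; split_val[nd.id] = best_thr;
    left[nd.id] = lid; right[nd.id] = rid;
    stack.push_back({lid, nd.lo, nd.lo + nL});
    stack.push_back({rid, nd.lo + nL, nd.hi});
  }
  (void)pre;
  return List::create(_["split_var"] = wrap(split_var),
                      _["split_val"] = wrap(split_val),
                      _["left"] = wrap(left),
                      _["right"] = wrap(right));
}

// Leaf (node index, 0-based) reached by each row of X.
// [[Rcpp::export]]
IntegerVector cpp_tree_leaves(IntegerVector split_var, NumericVector split_val,
                              IntegerVector left, IntegerVector right,
                              NumericMatrix X) {
  int n = X.nrow();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    int node = 0;
    while (split_var[node] >= 0) {
      node = (X(i, split_var[node]) <= split_val[node]) ? left[node]
                                                        : right[node];
    }
    out[i] = node;
  }
  return out;
}
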