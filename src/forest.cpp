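// Tree growing for the survival forest (log-rank splits, Nelson-Aalen
// terminal estimators) and the regression-forest comparator (RSS splits,
// mean-value terminals). One call grows one tree from a bootstrap sample;
// bagging, seeds and out-of-bag bookkeeping live on the R side. Variable
// subsampling uses R's RNG so a single set.seed() determines the forest.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

struct TreeBuild {
  std::vector<int> split_var;   // -1 => terminal, `left` holds terminal index
  std::vector<double> split_val;
  std::vector<int> left_kid, right_kid;
  std::vector<std::vector<double> > term_chf;  // survival terminals
  std::vector<double> term_value;              // regression terminals
};

struct Grower {
  const NumericMatrix& X;
  const NumericVector& time;
  const IntegerVector& event;
  const NumericVector& grid;  // global distinct event times (survival)
  int mtry, max_depth;
  bool survival;
  int min_deaths;     // d0: a child must hold > d0 unique event times
  int min_node_size;  // regression: minimum cases per child
  std::vector<int> cases;
  TreeBuild out;

  Grower(const NumericMatrix& X_, const NumericVector& time_,
         const IntegerVector& event_, const NumericVector& grid_)
      : X(X_), time(time_), event(event_), grid(grid_) {}

  int new_node() {
    out.split_var.push_back(-1);
    out.split_val.push_back(0.0);
    out.left_kid.push_back(-1);
    out.right_kid.push_back(-1);
    return (int)out.split_var.size() - 1;
  }

  // distinct event times among cases[lo, hi)
  void node_event_table(int lo, int hi, std::vector<double>& et,
                        std::vector<double>& d, std::vector<double>& n_risk) {
    et.clear();
    for (int k = lo; k < hi; ++k)
      if (event[cases[k]]) et.push_back(time[cases[k]]);
    std::sort(et.begin(), et.end());
    et.erase(std::unique(et.begin(), et.end()), et.end());
    size_t m = et.size();
    d.assign(m, 0.0);
    n_risk.assign(m, 0.0);
    for (int k = lo; k < hi; ++k) {
      double t = time[cases[k]];
      // all event times <= t have this case at risk
      size_t j = std::upper_bound(et.begin(), et.end(), t) - et.begin();
      for (size_t q = 0; q < j; ++q) n_risk[q] += 1.0;
      if (event[cases[k]]) {
        size_t pos = std::lower_bound(et.begin(), et.end(), t) - et.begin();
        d[pos] += 1.0;
      }
    }
  }

  int make_terminal(int lo, int hi) {
    int node = new_node();
    if (survival) {
      std::vector<double> et, d, n_risk;
      node_event_table(lo, hi, et, d, n_risk);
      std::vector<double> chf(grid.size(), 0.0);
      double cum = 0.0;
      size_t j = 0;
      for (int g = 0; g < grid.size(); ++g) {
        while (j < et.size() && et[j] <= grid[g]) {
          cum += d[j] / n_risk[j];
          ++j;
        }
        chf[g] = cum;
      }
      out.term_chf.push_back(chf);
      out.left_kid[node] = (int)out.term_chf.size() - 1;
    } else {
      // sorted accumulation keeps the mean invariant to case order
      std::vector<double> ys;
      ys.reserve(hi - lo);
      for (int k = lo; k < hi; ++k) ys.push_back(time[cases[k]]);
      std::sort(ys.begin(), ys.end());
      double s = 0.0;
      for (size_t k = 0; k < ys.size(); ++k) s += ys[k];
      out.term_value.push_back(s / ys.size());
      out.left_kid[node] = (int)out.term_value.size() - 1;
    }
    return node;
  }

  // ---- survival split search -------------------------------------------
  bool best_split_survival(int lo, int hi, const std::vector<int>& vars,
                           int& bvar, double& bval) {
    std::vector<double> et, d, n_risk;
    node_event_table(lo, hi, et, d, n_risk);
    size_t m = et.size();
    if ((int)m < min_deaths) return false;  // no child can reach d0
    double best_abs = -1.0;
    bvar = -1;
    int nn = hi - lo;
    std::vector<std::pair<double, int> > vv(nn);  // (value, case)
    std::vector<double> nL(m), dL(m);
    for (size_t vi = 0; vi < vars.size(); ++vi) {
      int v = vars[vi];
      for (int k = 0; k < nn; ++k) {
        int c = cases[lo + k];
        vv[k] = std::make_pair(X(c, v), c);
      }
      std::sort(vv.begin(), vv.end());
      if (vv.front().first == vv.back().first) continue;
      std::fill(nL.begin(), nL.end(), 0.0);
      std::fill(dL.begin(), dL.end(), 0.0);
      int k = 0;
      while (k < nn) {
        double val = vv[k].first;
        while (k < nn && vv[k].first == val) {
          int c = vv[k].second;
          double t = time[c];
          size_t j = std::upper_bound(et.begin(), et.end(), t) - et.begin();
          for (size_t q = 0; q < j; ++q) nL[q] += 1.0;
          if (event[c]) {
            size_t pos = std::lower_bound(et.begin(), et.end(), t) - et.begin();
            dL[pos] += 1.0;
          }
          ++k;
        }
        if (k >= nn) break;  // last distinct value: no cut to the right
        // child validity: both daughters must hold >= d0 unique event times
        int deaths_l = 0, deaths_r = 0;
        for (size_t q = 0; q < m; ++q) {
          if (dL[q] > 0) ++deaths_l;
          if (d[q] - dL[q] > 0) ++deaths_r;
        }
        if (deaths_l >= min_deaths && deaths_r >= min_deaths) {
          double u = 0.0, var_sum = 0.0;
          for (size_t q = 0; q < m; ++q) {
            u += dL[q] - d[q] * nL[q] / n_risk[q];
            if (n_risk[q] > 1) {
              double p = nL[q] / n_risk[q];
              var_sum += d[q] * p * (1.0 - p) *
                         (n_risk[q] - d[q]) / (n_risk[q] - 1.0);
            }
          }
          if (var_sum > 0) {
            double stat = std::fabs(u / std::sqrt(var_sum));
            if (stat > best_abs) {  // strict: earlier var/cut wins ties
              best_abs = stat;
              bvar = v;
              bval = (val + vv[k].first) / 2.0;
            }
          }
        }
      }
    }
    return bvar >= 0;
  }

  // ---- regression split search -----------------------------------------
  bool best_split_regression(int lo, int hi, const std::vector<int>& vars,
                             int& bvar, double& bval) {
    int nn = hi - lo;
    if (nn < 2 * min_node_size) return false;
    double best_crit = -1.0;
    bvar = -1;
    std::vector<std::pair<double, double> > vy(nn);  // (value, target)
    for (size_t vi = 0; vi < vars.size(); ++vi) {
      int v = vars[vi];
      double s_tot = 0.0;
      for (int k = 0; k < nn; ++k) {
        int c = cases[lo + k];
        vy[k] = std::make_pair(X(c, v), time[c]);
        s_tot += time[c];
      }
      std::sort(vy.begin(), vy.end());
      if (vy.front().first == vy.back().first) continue;
      double s_left = 0.0;
      int k = 0;
      while (k < nn) {
        double val = vy[k].first;
        while (k < nn && vy[k].first == val) {
          s_left += vy[k].second;
          ++k;
        }
        if (k >= nn) break;
        int nl = k, nr = nn - k;
        if (nl < min_node_size || nr < min_node_size) continue;
        double s_right = s_tot - s_left;
        // between-group sum of squares == RSS reduction of the split
        double crit = s_left * s_left / nl + s_right * s_right / nr -
                      s_tot * s_tot / nn;
        if (crit > best_crit + 1e-12 * std::max(1.0, std::fabs(best_crit))) {
          best_crit = crit;
          bvar = v;
          bval = (val + vy[k].first) / 2.0;
        }
      }
    }
    return bvar >= 0 && best_crit > 1e-12;
  }

  int grow(int lo, int hi, int depth) {
    int p = X.ncol();
    bool can_split = (max_depth < 0 || depth < max_depth) && (hi - lo) >= 2;
    int bvar = -1;
    double bval = 0.0;
    if (can_split) {
      // sampled without replacement, ascending => ties resolve to the
      // lowest variable index, then the lowest cut value
      IntegerVector draw = Rcpp::sample(p, std::min(mtry, p));
      std::vector<int> vars(draw.begin(), draw.end());
      for (size_t i = 0; i < vars.size(); ++i) vars[i] -= 1;
      std::sort(vars.begin(), vars.end());
      bool found = survival ? best_split_survival(lo, hi, vars, bvar, bval)
                            : best_split_regression(lo, hi, vars, bvar, bval);
      if (!found) bvar = -1;
    }
    if (bvar < 0) return make_terminal(lo, hi);
    int v = bvar;
    double cut = bval;
    const NumericMatrix& Xr = X;
    std::vector<int>::iterator first = cases.begin() + lo,
                               last = cases.begin() + hi;
    std::vector<int>::iterator mid = std::partition(
        first, last, [&](int c) { return Xr(c, v) <= cut; });
    int split_at = (int)(mid - cases.begin());
    int node = new_node();
    out.split_var[node] = bvar;
    out.split_val[node] = bval;
    int l = grow(lo, split_at, depth + 1);
    int r = grow(split_at, hi, depth + 1);
    out.left_kid[node] = l;
    out.right_kid[node] = r;
    return node;
  }
};

}  // namespace

// [[Rcpp::export]]
List grow_tree_cpp(NumericMatrix X, NumericVector time, IntegerVector event,
                   IntegerVector inbag, int mtry, bool survival,
                   int min_deaths, int min_node_size, int max_depth,
                   NumericVector grid) {
  Grower g(X, time, event, grid);
  g.mtry = mtry;
  g.survival = survival;
  g.min_deaths = min_deaths;
  g.min_node_size = min_node_size;
  g.max_depth = max_depth;
  g.cases.assign(inbag.begin(), inbag.end());
  int root = g.grow(0, (int)g.cases.size(), 0);
  if (root != 0) stop("internal error: root node is not node 0");

  List tree = List::create(
      Named("split_var") = wrap(g.out.split_var),
      Named("split_val") = wrap(g.out.split_val),
      Named("left") = wrap(g.out.left_kid),
      Named("right") = wrap(g.out.right_kid));
  if (survival) {
    int nt = (int)g.out.term_chf.size();
    NumericMatrix chf(nt, grid.size());
    for (int i = 0; i < nt; ++i)
      for (int j = 0; j < grid.size(); ++j) chf(i, j) = g.out.term_chf[i][j];
    tree["terminal_chf"] = chf;
  } else {
    tree["terminal_value"] = wrap(g.out.term_value);
  }
  return tree;
}

// Drop each row of X through the tree; returns 1-based terminal indices.
// [[Rcpp::export]]
IntegerVector predict_terminal_cpp(IntegerVector split_var,
                                   NumericVector split_val, IntegerVector left,
                                   IntegerVector right, NumericMatrix X) {
  int n = X.nrow();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    int node = 0;
    while (split_var[node] >= 0) {
      node = (X(i, split_var[node]) <= split_val[node]) ? left[node]
                                                        : right[node];
    }
    out[i] = left[node] + 1;
  }
  return out;
}
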