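#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <random>
#include <vector>
using namespace Rcpp;

namespace {

// Survival bookkeeping for one node, on the node's own distinct event times.
// Bootstrap multiplicities enter as integer weights (Breslow handling of ties:
// tied events are aggregated at their common time).
struct NodeSurv {
  std::vector<double> etimes;  // distinct event times, ascending
  std::vector<double> d;       // weighted event count at each event time
  std::vector<double> natrisk; // weighted number at risk at each event time
  std::vector<int> kcount;     // per member: #event times <= member's time
  std::vector<int> eidx;       // per member: index of own event time, -1 if censored
};

void build_node_surv(const std::vector<int> &members, const NumericVector &time,
                     const IntegerVector &event, const IntegerVector &w,
                     NodeSurv &ns) {
  ns.etimes.clear();
  for (int i : members)
    if (event[i] == 1) ns.etimes.push_back(time[i]);
  std::sort(ns.etimes.begin(), ns.etimes.end());
  ns.etimes.erase(std::unique(ns.etimes.begin(), ns.etimes.end()),
                  ns.etimes.end());
  const int E = (int)ns.etimes.size();
  ns.d.assign(E, 0.0);
  ns.natrisk.assign(E, 0.0);
  ns.kcount.assign(members.size(), 0);
  ns.eidx.assign(members.size(), -1);
  for (size_t m = 0; m < members.size(); ++m) {
    const int i = members[m];
    const int k = (int)(std::upper_bound(ns.etimes.begin(), ns.etimes.end(),
                                         time[i]) -
                        ns.etimes.begin());
    ns.kcount[m] = k;
    for (int j = 0; j < k; ++j) ns.natrisk[j] += w[i];
    if (event[i] == 1) {
      const int e = (int)(std::lower_bound(ns.etimes.begin(), ns.etimes.end(),
                                           time[i]) -
                          ns.etimes.begin());
      ns.eidx[m] = e;
      ns.d[e] += w[i];
    }
  }
}

// Best standardized log-rank split on predictor v within the node.
// Thresholds are midpoints between consecutive distinct observed values;
// the sweep maintains left-group at-risk/event tables incrementally.
bool best_split_for_var(const std::vector<int> &members, const NodeSurv &ns,
                        const NumericMatrix &X, const IntegerVector &w, int v,
                        double &best_stat, double &best_thr) {
  const int s = (int)members.size();
  const int E = (int)ns.etimes.size();
  if (E == 0 || s < 2) return false;
  std::vector<int> ord(s);
  for (int m = 0; m < s; ++m) ord[m] = m;
  std::stable_sort(ord.begin(), ord.end(), [&](int a, int b) {
    return X(members[a], v) < X(members[b], v);
  });
  std::vector<double> n1(E, 0.0), d1(E, 0.0);
  bool found = false;
  for (int jj = 0; jj < s - 1; ++jj) {
    const int m = ord[jj];
    const int i = members[m];
    for (int k = 0; k < ns.kcount[m]; ++k) n1[k] += w[i];
    if (ns.eidx[m] >= 0) d1[ns.eidx[m]] += w[i];
    const double xa = X(members[ord[jj]], v);
    const double xb = X(members[ord[jj + 1]], v);
    if (!(xb > xa)) continue; // only distinct-value boundaries
    double num = 0.0, var = 0.0;
    for (int k = 0; k < E; ++k) {
      const double nk = ns.natrisk[k], dk = ns.d[k];
      if (nk <= 0) continue;
      num += d1[k] - n1[k] * dk / nk;
      if (nk > 1)
        var += dk * (nk - dk) / (nk - 1.0) * n1[k] * (nk - n1[k]) / (nk * nk);
    }
    if (var <= 0) continue;
    const double stat = std::fabs(num) / std::sqrt(var);
    if (!found || stat > best_stat) {
      best_stat = stat;
      best_thr = 0.5 * (xa + xb);
      found = true;
    }
  }
  return found;
}

// Nelson-Aalen cumulative hazard of the node members on the shared grid.
void terminal_chf(const NodeSurv &ns, const NumericVector &grid, double *out) {
  const int G = grid.size();
  const int E = (int)ns.etimes.size();
  double h = 0.0;
  int k = 0;
  for (int g = 0; g < G; ++g) {
    while (k < E && ns.etimes[k] <= grid[g]) {
      if (ns.natrisk[k] > 0) h += ns.d[k] / ns.natrisk[k];
      ++k;
    }
    out[g] = h;
  }
}

struct NodeTask {
  std::vector<int> members;
  int depth;
  int id;
};

// Harrell's C on a subset: permissible pair (i, j) when t_i < t_j and
// subject i had the event; risk ties count 1/2. Returns -1 when no
// permissible pair exists.
double concordance(const std::vector<double> &t, const std::vector<int> &e,
                   const std::vector<double> &r) {
  const int n = (int)t.size();
  double conc = 0.0;
  long perm = 0;
  for (int i = 0; i < n; ++i) {
    if (e[i] != 1) continue;
    for (int j = 0; j < n; ++j) {
      if (t[i] < t[j]) {
        ++perm;
        if (r[i] > r[j])
          conc += 1.0;
        else if (r[i] == r[j])
          conc += 0.5;
      }
    }
  }
  if (perm == 0) return -1.0;
  return conc / (double)perm;
}

inline int drop_row(const IntegerVector &svar, const NumericVector &sval,
                    const IntegerVector &left, const IntegerVector &right,
                    const NumericMatrix &X, int i) {
  int node = 0;
  while (svar[node] >= 0)
    node = (X(i, svar[node]) <= sval[node]) ? left[node] : right[node];
  return node;
}

// Traversal with one predictor's value overridden (for permutation VIMP).
inline int drop_row_override(const IntegerVector &svar,
                             const NumericVector &sval,
                             const IntegerVector &left,
                             const IntegerVector &right,
                             const NumericMatrix &X, int i, int col,
                             double val) {
  int node = 0;
  while (svar[node] >= 0) {
    const double x = (svar[node] == col) ? val : X(i, svar[node]);
    node = (x <= sval[node]) ? left[node] : right[node];
  }
  return node;
}

} // namespace

// Grow a single survival tree on the in-bag sample (inbag = bootstrap
// multiplicities; 0 = out of bag). Nodes split on the candidate predictor /
// midpoint threshold maximizing the standardized log-rank statistic; among
// equal statistics the first candidate in the seeded random draw order wins.
// A node is terminal when its (weighted) size or event count falls below the
// configured minima or no admissible split exists. Terminal nodes store the
// Nelson-Aalen cumulative hazard of their members on the shared event-time
// grid. Predictor indices in the output are 0-based, -1 marking terminals.
// [[Rcpp::export]]
List grow_tree_cpp(NumericMatrix X, NumericVector time, IntegerVector event,
                   IntegerVector inbag, NumericVector grid, int mtry,
                   double min_node_size, double min_node_events, int seed) {
  const int n = X.nrow();
  const int p = X.ncol();
  const int G = grid.size();
  std::mt19937 rng((uint32_t)seed);

  std::vector<int> svar, sleft, sright, sdepth;
  std::vector<double> sval;
  std::vector<std::vector<double>> chfs;
  auto new_node = [&](int depth) {
    svar.push_back(-1);
    sval.push_back(0.0);
    sleft.push_back(-1);
    sright.push_back(-1);
    sdepth.push_back(depth);
    chfs.push_back(std::vector<double>());
    return (int)(svar.size() - 1);
  };

  std::vector<int> root;
  for (int i = 0; i < n; ++i)
    if (inbag[i] > 0) root.push_back(i);
  std::vector<NodeTask> todo;
  todo.push_back({std::move(root), 0, new_node(0)});

  std::vector<int> varpool(p);
  for (int v = 0; v < p; ++v) varpool[v] = v;

  while (!todo.empty()) {
    NodeTask nt = std::move(todo.back());
    todo.pop_back();
    NodeSurv ns;
    build_node_surv(nt.members, time, event, inbag, ns);
    double S = 0.0, D = 0.0;
    for (int i : nt.members) {
      S += inbag[i];
      if (event[i] == 1) D += inbag[i];
    }
    bool terminal =
        (S < min_node_size) || (D < min_node_events) || ns.etimes.empty();
    int bestv = -1;
    double best_stat = 0.0, best_thr = 0.0;
    if (!terminal) {
      const int m = std::min(mtry, p);
      for (int j = 0; j < m; ++j) {
        std::uniform_int_distribution<int> U(j, p - 1);
        const int t = U(rng);
        std::swap(varpool[j], varpool[t]);
        const int v = varpool[j];
        double st = 0.0, th = 0.0;
        if (best_split_for_var(nt.members, ns, X, inbag, v, st, th) &&
            st > 0.0 && (bestv < 0 || st > best_stat)) {
          bestv = v;
          best_stat = st;
          best_thr = th;
        }
      }
      if (bestv < 0) terminal = true;
    }
    if (terminal) {
      chfs[nt.id].resize(G);
      terminal_chf(ns, grid, chfs[nt.id].data());
      continue;
    }
    std::vector<int> lm, rm;
    for (int i : nt.members)
      (X(i, bestv) <= best_thr ? lm : rm).push_back(i);
    const int lid = new_node(nt.depth + 1);
    const int rid = new_node(nt.depth + 1);
    svar[nt.id] = bestv;
    sval[nt.id] = best_thr;
    sleft[nt.id] = lid;
    sright[nt.id] = rid;
    todo.push_back({std::move(lm), nt.depth + 1, lid});
    todo.push_back({std::move(rm), nt.depth + 1, rid});
  }

  const int nn = (int)svar.size();
  NumericMatrix chf(nn, G);
  for (int q = 0; q < nn; ++q)
    if (!chfs[q].empty())
      for (int g = 0; g < G; ++g) chf(q, g) = chfs[q][g];
  return List::create(_["split_var"] = wrap(svar), _["split_val"] = wrap(sval),
                      _["left"] = wrap(sleft), _["right"] = wrap(sright),
                      _["depth"] = wrap(sdepth), _["chf"] = chf);
}

// Ensemble cumulative hazard: average over member trees of the terminal-node
// CHF reached by each row of X. Rows x grid-points.
// [[Rcpp::export]]
NumericMatrix ensemble_chf_cpp(List trees, NumericMatrix X) {
  const int n = X.nrow();
  const int T = trees.size();
  List t0 = trees[0];
  NumericMatrix chf0 = t0["chf"];
  const int G = chf0.ncol();
  NumericMatrix out(n, G);
  for (int t = 0; t < T; ++t) {
    List tr = trees[t];
    IntegerVector svar = tr["split_var"];
    NumericVector sval = tr["split_val"];
    IntegerVector lf = tr["left"], rt = tr["right"];
    NumericMatrix chf = tr["chf"];
    for (int i = 0; i < n; ++i) {
      const int node = drop_row(svar, sval, lf, rt, X, i);
      for (int g = 0; g < G; ++g) out(i, g) += chf(node, g);
    }
  }
  const double inv = 1.0 / (double)T;
  for (int i = 0; i < n; ++i)
    for (int g = 0; g < G; ++g) out(i, g) *= inv;
  return out;
}

// Out-of-bag ensemble mortality: per subject, the mean over trees for which
// the subject is OOB of the terminal CHF summed over the grid. NA for
// subjects that are in-bag in every tree.
// [[Rcpp::export]]
NumericVector oob_mortality_cpp(List trees, List oob, NumericMatrix X) {
  const int n = X.nrow();
  const int T = trees.size();
  std::vector<double> acc(n, 0.0);
  std::vector<int> cnt(n, 0);
  for (int t = 0; t < T; ++t) {
    List tr = trees[t];
    IntegerVector svar = tr["split_var"];
    NumericVector sval = tr["split_val"];
    IntegerVector lf = tr["left"], rt = tr["right"];
    NumericMatrix chf = tr["chf"];
    IntegerVector ob = oob[t];
    const int G = chf.ncol();
    for (int jj = 0; jj < ob.size(); ++jj) {
      const int i = ob[jj] - 1; // 1-based from R
      const int node = drop_row(svar, sval, lf, rt, X, i);
      double s = 0.0;
      for (int g = 0; g < G; ++g) s += chf(node, g);
      acc[i] += s;
      cnt[i] += 1;
    }
  }
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = cnt[i] > 0 ? acc[i] / cnt[i] : NA_REAL;
  return out;
}

// Tree-wise permutation importance (Breiman-Cutler / the standard RSF
// scheme): for each tree, the OOB prediction error (1 - Harrell's C of the
// tree's terminal-node mortality on its OOB subjects) is recomputed after
// permuting the predictor's OOB values within that tree, and the error
// differences are averaged over trees (and over `n_repeats` independent
// permutation rounds). Trees whose OOB set has no permissible pair are
// skipped. Returns one value per requested column (0-based indices).
// [[Rcpp::export]]
NumericVector tree_vimp_cpp(List trees, List oob, NumericMatrix X,
                            NumericVector time, IntegerVector event,
                            IntegerVector cols, int n_repeats, int seed) {
  const int T = trees.size();
  std::mt19937 rng((uint32_t)seed);

  // cache per tree: OOB indices, terminal mortality, baseline error
  std::vector<std::vector<int>> oob_idx(T);
  std::vector<std::vector<double>> oob_time(T), oob_mort(T);
  std::vector<std::vector<int>> oob_event(T);
  std::vector<double> base_err(T, -1.0);
  for (int t = 0; t < T; ++t) {
    List tr = trees[t];
    IntegerVector svar = tr["split_var"];
    NumericVector sval = tr["split_val"];
    IntegerVector lf = tr["left"], rt = tr["right"];
    NumericMatrix chf = tr["chf"];
    IntegerVector ob = oob[t];
    const int G = chf.ncol();
    const int m = ob.size();
    oob_idx[t].resize(m);
    oob_time[t].resize(m);
    oob_event[t].resize(m);
    oob_mort[t].resize(m);
    for (int jj = 0; jj < m; ++jj) {
      const int i = ob[jj] - 1;
      oob_idx[t][jj] = i;
      oob_time[t][jj] = time[i];
      oob_event[t][jj] = event[i];
      const int node = drop_row(svar, sval, lf, rt, X, i);
      double s = 0.0;
      for (int g = 0; g < G; ++g) s += chf(node, g);
      oob_mort[t][jj] = s;
    }
    const double c = concordance(oob_time[t], oob_event[t], oob_mort[t]);
    base_err[t] = (c < 0) ? -1.0 : 1.0 - c;
  }

  NumericVector out(cols.size());
  std::vector<double> xperm, mort;
  for (int ci = 0; ci < cols.size(); ++ci) {
    const int v = cols[ci];
    double total = 0.0;
    long used = 0;
    for (int rep = 0; rep < n_repeats; ++rep) {
      for (int t = 0; t < T; ++t) {
        if (base_err[t] < 0) continue;
        List tr = trees[t];
        IntegerVector svar = tr["split_var"];
        NumericVector sval = tr["split_val"];
        IntegerVector lf = tr["left"], rt = tr["right"];
        NumericMatrix chf = tr["chf"];
        const int G = chf.ncol();
        const int m = (int)oob_idx[t].size();
        xperm.resize(m);
        for (int jj = 0; jj < m; ++jj) xperm[jj] = X(oob_idx[t][jj], v);
        for (int jj = m - 1; jj > 0; --jj) {
          std::uniform_int_distribution<int> U(0, jj);
          std::swap(xperm[jj], xperm[U(rng)]);
        }
        mort.resize(m);
        for (int jj = 0; jj < m; ++jj) {
          const int node = drop_row_override(svar, sval, lf, rt, X,
                                             oob_idx[t][jj], v, xperm[jj]);
          double s = 0.0;
          for (int g = 0; g < G; ++g) s += chf(node, g);
          mort[jj] = s;
        }
        const double c = concordance(oob_time[t], oob_event[t], mort);
        if (c < 0) continue;
        total += (1.0 - c) - base_err[t];
        ++used;
      }
    }
    out[ci] = used > 0 ? total / (double)used : NA_REAL;
  }
  return out;
}

// OOB ensemble mortality with predictor `col` (0-based) permuted within
// each tree's OOB set: perm_vals[t] holds the permuted values aligned with
// oob[[t]]. This is the noise-reduced per-tree permutation scheme of
// permutation importance: every tree sees an independent permutation.
// [[Rcpp::export]]
NumericVector oob_mortality_perm_cpp(List trees, List oob, NumericMatrix X,
                                     int col, List perm_vals) {
  const int n = X.nrow();
  const int T = trees.size();
  std::vector<double> acc(n, 0.0);
  std::vector<int> cnt(n, 0);
  for (int t = 0; t < T; ++t) {
    List tr = trees[t];
    IntegerVector svar = tr["split_var"];
    NumericVector sval = tr["split_val"];
    IntegerVector lf = tr["left"], rt = tr["right"];
    NumericMatrix chf = tr["chf"];
    IntegerVector ob = oob[t];
    NumericVector pv = perm_vals[t];
    const int G = chf.ncol();
    for (int jj = 0; jj < ob.size(); ++jj) {
      const int i = ob[jj] - 1;
      const int node =
          drop_row_override(svar, sval, lf, rt, X, i, col, pv[jj]);
      double s = 0.0;
      for (int g = 0; g < G; ++g) s += chf(node, g);
      acc[i] += s;
      cnt[i] += 1;
    }
  }
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = cnt[i] > 0 ? acc[i] / cnt[i] : NA_REAL;
  return out;
}
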