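// Classification random forest on SNP dosage codes {0, 0.5, 1}, grown with
// threshold splits at the dosage midpoints, plus the sequentially regularized
// variant in which a shared selected-feature set accumulates across trees.
// All randomness comes from a self-contained 64-bit counter RNG so that a
// given seed yields bit-identical forests on any platform.

#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

namespace {

// splitmix64: tiny, well-mixed, platform-independent
struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed) {}
  uint64_t next() {
    uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  int randint(int n) {  // uniform on 0..n-1
    int r = static_cast<int>(unif() * n);
    return r >= n ? n - 1 : r;
  }
};

struct Tree {
  std::vector<int> feature;      // -1 for leaf
  std::vector<double> thr;
  std::vector<int> left, right;
  std::vector<int> pred;         // leaf class, -1 for internal
};

const double MIDPOINTS[2] = {0.25, 0.75};

inline double gini_from_counts(const std::vector<int>& cnt, int K, int n) {
  if (n == 0) return 0.0;
  double g = 1.0;
  for (int k = 0; k < K; ++k) {
    double f = static_cast<double>(cnt[k]) / n;
    g -= f * f;
  }
  return g;
}

int majority_class(const std::vector<int>& cnt, int K) {
  int best = 0;
  for (int k = 1; k < K; ++k) if (cnt[k] > cnt[best]) best = k;
  return best;  // ties fall to the lowest class index
}

struct SplitChoice {
  int feature = -1;
  double thr = 0.0;
  double raw_gain = -1.0;   // unpenalized Gini decrease
  double score = -1.0;      // penalized gain used for comparison
  bool in_set = false;      // feature already in the selected set
};

// Evaluate both midpoint thresholds of one feature; update the running best.
// Tie rule: higher score wins; at equal score an already-selected feature
// beats a new one; remaining ties go to the lowest feature index, then to the
// lower threshold.
void consider_feature(const NumericMatrix& X, const IntegerVector& y, int K,
                      const std::vector<int>& samp, int start, int end,
                      int f, double penalty, bool in_set,
                      double parent_gini, SplitChoice& best) {
  int n = end - start;
  // class counts in three dosage bins: <0.25, [0.25,0.75), >=0.75
  std::vector<int> bin(3 * K, 0);
  for (int i = start; i < end; ++i) {
    int id = samp[i];
    double v = X(id, f);
    int b = v < 0.25 ? 0 : (v < 0.75 ? 1 : 2);
    bin[b * K + y[id]]++;
  }
  std::vector<int> lc(K), rc(K);
  for (int t = 0; t < 2; ++t) {
    int nl = 0, nr = 0;
    for (int k = 0; k < K; ++k) {
      lc[k] = bin[k] + (t == 1 ? bin[K + k] : 0);
      rc[k] = (t == 0 ? bin[K + k] : 0) + bin[2 * K + k];
      nl += lc[k];
      nr += rc[k];
    }
    if (nl == 0 || nr == 0) continue;
    double gain = parent_gini -
      (static_cast<double>(nl) / n) * gini_from_counts(lc, K, nl) -
      (static_cast<double>(nr) / n) * gini_from_counts(rc, K, nr);
    if (gain < 1e-12) continue;
    double score = in_set ? gain : gain * penalty;
    bool better = false;
    if (score > best.score) {
      better = true;
    } else if (score == best.score) {
      if (in_set && !best.in_set) better = true;
      else if (in_set == best.in_set) {
        if (f < best.feature) better = true;
        else if (f == best.feature && MIDPOINTS[t] < best.thr) better = true;
      }
    }
    if (better) {
      best.feature = f;
      best.thr = MIDPOINTS[t];
      best.raw_gain = gain;
      best.score = score;
      best.in_set = in_set;
    }
  }
}

// Grow one tree on the bootstrap sample held in samp[0..n). When `lam` is
// non-null the regularized rule is used: candidates are the mtry sampled
// features plus every feature already in F; non-members have their gain
// multiplied by lam[f]; the winning feature joins F.
void grow_tree(const NumericMatrix& X, const IntegerVector& y, int K,
               std::vector<int>& samp, int mtry, int min_node, Rng& rng,
               std::vector<int>& perm,
               const std::vector<double>* lam,
               std::vector<char>* in_f, std::vector<int>* f_order,
               Tree& tr) {
  int p = X.ncol();
  struct NodeJob { int node, start, end; };
  std::vector<NodeJob> stack;
  tr.feature.assign(1, -1);
  tr.thr.assign(1, 0.0);
  tr.left.assign(1, -1);
  tr.right.assign(1, -1);
  tr.pred.assign(1, -1);
  stack.push_back({0, 0, static_cast<int>(samp.size())});
  std::vector<int> cnt(K);
  std::vector<int> swaps;
  std::vector<int> buf;
  std::vector<char> sampled_mark(p, 0);

  while (!stack.empty()) {
    NodeJob jb = stack.back();
    stack.pop_back();
    int n = jb.end - jb.start;
    std::fill(cnt.begin(), cnt.end(), 0);
    for (int i = jb.start; i < jb.end; ++i) cnt[y[samp[i]]]++;
    int nz = 0;
    for (int k = 0; k < K; ++k) if (cnt[k] > 0) nz++;
    if (nz <= 1 || n <= min_node) {
      tr.pred[jb.node] = majority_class(cnt, K);
      continue;
    }
    double parent_gini = gini_from_counts(cnt, K, n);

    // sample mtry distinct features by partial Fisher-Yates with undo
    swaps.clear();
    int m = mtry < p ? mtry : p;
    for (int i = 0; i < m; ++i) {
      int j = i + rng.randint(p - i);
      std::swap(perm[i], perm[j]);
      swaps.push_back(j);
    }
    SplitChoice best;
    for (int i = 0; i < m; ++i) {
      int f = perm[i];
      if (lam) sampled_mark[f] = 1;
      bool in_set = lam && (*in_f)[f];
      double penalty = lam ? (*lam)[f] : 1.0;
      consider_feature(X, y, K, samp, jb.start, jb.end, f, penalty, in_set,
                       parent_gini, best);
    }
    if (lam) {
      for (size_t i = 0; i < f_order->size(); ++i) {
        int f = (*f_order)[i];
        if (sampled_mark[f]) continue;
        consider_feature(X, y, K, samp, jb.start, jb.end, f, 1.0, true,
                         parent_gini, best);
      }
      for (int i = 0; i < m; ++i) sampled_mark[perm[i]] = 0;
    }
    for (int i = m - 1; i >= 0; --i) std::swap(perm[i], perm[swaps[i]]);

    if (best.feature < 0) {
      tr.pred[jb.node] = majority_class(cnt, K);
      continue;
    }
    if (lam && !(*in_f)[best.feature]) {
      (*in_f)[best.feature] = 1;
      f_order->push_back(best.feature);
    }

    // deterministic stable partition of samp[start,end) on the split
    buf.clear();
    int mid = jb.start;
    for (int i = jb.start; i < jb.end; ++i) {
      int id = samp[i];
      if (X(id, best.feature) < best.thr) samp[mid++] = id;
      else buf.push_back(id);
    }
    for (size_t i = 0; i < buf.size(); ++i) samp[mid + i] = buf[i];

    int li = tr.feature.size(), ri = li + 1;
    for (int c = 0; c < 2; ++c) {
      tr.feature.push_back(-1);
      tr.thr.push_back(0.0);
      tr.left.push_back(-1);
      tr.right.push_back(-1);
      tr.pred.push_back(-1);
    }
    tr.feature[jb.node] = best.feature;
    tr.thr[jb.node] = best.thr;
    tr.left[jb.node] = li;
    tr.right[jb.node] = ri;
    // push right first so the left child is grown first (pure convention)
    stack.push_back({ri, mid, jb.end});
    stack.push_back({li, jb.start, mid});
  }
}

inline int predict_case(const Tree& tr, const NumericMatrix& X, int i,
                        int override_f = -1, double ov = 0.0) {
  int node = 0;
  while (tr.feature[node] >= 0) {
    int f = tr.feature[node];
    double v = (f == override_f) ? ov : X(i, f);
    node = v < tr.thr[node] ? tr.left[node] : tr.right[node];
  }
  return tr.pred[node];
}

inline int leaf_of_case(const Tree& tr, const NumericMatrix& X, int i) {
  int node = 0;
  while (tr.feature[node] >= 0)
    node = X(i, tr.feature[node]) < tr.thr[node] ? tr.left[node] : tr.right[node];
  return node;
}

List tree_to_list(const Tree& tr) {
  return List::create(_["feature"] = wrap(tr.feature),
                      _["threshold"] = wrap(tr.thr),
                      _["left"] = wrap(tr.left),
                      _["right"] = wrap(tr.right),
                      _["pred"] = wrap(tr.pred));
}

Tree tree_from_list(const List& li) {
  Tree tr;
  tr.feature = as<std::vector<int> >(li["feature"]);
  tr.thr = as<std::vector<double> >(li["threshold"]);
  tr.left = as<std::vector<int> >(li["left"]);
  tr.right = as<std::vector<int> >(li["right"]);
  tr.pred = as<std::vector<int> >(li["pred"]);
  return tr;
}

// shared driver for plain and regularized forests
List grow_forest_impl(const NumericMatrix& X, const IntegerVector& y, int K,
                      int ntree, int mtry, int min_node, double seed,
                      const std::vector<double>* lam) {
  int n = X.nrow(), p = X.ncol();
  Rng rng(static_cast<uint64_t>(seed));
  std::vector<int> perm(p);
  for (int f = 0; f < p; ++f) perm[f] = f;
  std::vector<char> in_f(p, 0);
  std::vector<int> f_order;

  List trees(ntree);
  List oob_list(ntree);
  std::vector<int> votes(n * K, 0);
  std::vector<int> inbag(n);
  std::vector<int> samp(n);
  Tree tr;

  for (int t = 0; t < ntree; ++t) {
    std::fill(inbag.begin(), inbag.end(), 0);
    for (int i = 0; i < n; ++i) {
      int id = rng.randint(n);
      samp[i] = id;
      inbag[id]++;
    }
    grow_tree(X, y, K, samp, mtry, min_node, rng, perm,
              lam, lam ? &in_f : 0, lam ? &f_order : 0, tr);
    std::vector<int> oob;
    for (int i = 0; i < n; ++i) if (inbag[i] == 0) oob.push_back(i);
    for (size_t j = 0; j < oob.size(); ++j)
      votes[oob[j] * K + predict_case(tr, X, oob[j])]++;
    IntegerVector ov(oob.begin(), oob.end());
    oob_list[t] = ov + 1;  // 1-based for R
    trees[t] = tree_to_list(tr);
  }

  IntegerVector oob_pred(n, NA_INTEGER);
  int n_scored = 0, n_wrong = 0;
  for (int i = 0; i < n; ++i) {
    int tot = 0, best = 0;
    for (int k = 0; k < K; ++k) {
      tot += votes[i * K + k];
      if (votes[i * K + k] > votes[i * K + best]) best = k;
    }
    if (tot > 0) {
      oob_pred[i] = best + 1;
      n_scored++;
      if (best != y[i]) n_wrong++;
    }
  }
  double oob_error = n_scored > 0 ? static_cast<double>(n_wrong) / n_scored
                                  : NA_REAL;
  List out = List::create(_["trees"] = trees,
                          _["oob"] = oob_list,
                          _["oob_pred"] = oob_pred,
                          _["oob_error"] = oob_error);
  if (lam) {
    IntegerVector sel(f_order.begin(), f_order.end());
    out["selected"] = sel + 1;
  }
  return out;
}

}  // namespace

// [[Rcpp::export]]
List cpp_grow_forest(NumericMatrix X, IntegerVector y, int n_class,
                     int ntree, int mtry, int min_node, double seed) {
  return grow_forest_impl(X, y, n_class, ntree, mtry, min_node, seed, 0);
}

// [[Rcpp::export]]
List cpp_grow_regularized(NumericMatrix X, IntegerVector y, int n_class,
                          int ntree, int mtry, int min_node, double seed,
                          NumericVector penalty) {
  std::vector<double> lam = as<std::vector<double> >(penalty);
  return grow_forest_impl(X, y, n_class, ntree, mtry, min_node, seed, &lam);
}

// [[Rcpp::export]]
IntegerVector cpp_predict_forest(List trees, NumericMatrix X, int n_class) {
  int n = X.nrow(), ntree = trees.size();
  std::vector<int> votes(n * n_class, 0);
  for (int t = 0; t < ntree; ++t) {
    Tree tr = tree_from_list(trees[t]);
    for (int i = 0; i < n; ++i) votes[i * n_class + predict_case(tr, X, i)]++;
  }
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    int best = 0;
    for (int k = 1; k < n_class; ++k)
      if (votes[i * n_class + k] > votes[i * n_class + best]) best = k;
    out[i] = best + 1;
  }
  return out;
}

// Permutation importance: per tree, OOB accuracy minus OOB accuracy after
// permuting one locus among that tree's OOB cases, averaged over trees with
// at least one OOB case. Loci untouched by a tree contribute an exact zero.
// [[Rcpp::export]]
NumericVector cpp_mda(List trees, List oob_list, NumericMatrix X,
                      IntegerVector y, double seed) {
  int p = X.ncol(), ntree = trees.size();
  NumericVector imp(p);
  Rng rng(static_cast<uint64_t>(seed));
  int trees_used = 0;
  std::vector<char> used(p);
  std::vector<double> permuted;
  for (int t = 0; t < ntree; ++t) {
    IntegerVector oob1 = oob_list[t];
    int m = oob1.size();
    if (m == 0) continue;
    trees_used++;
    Tree tr = tree_from_list(trees[t]);
    std::vector<int> oob(m);
    for (int j = 0; j < m; ++j) oob[j] = oob1[j] - 1;
    int correct0 = 0;
    for (int j = 0; j < m; ++j)
      if (predict_case(tr, X, oob[j]) == y[oob[j]]) correct0++;
    double acc0 = static_cast<double>(correct0) / m;
    std::fill(used.begin(), used.end(), 0);
    for (size_t nd = 0; nd < tr.feature.size(); ++nd)
      if (tr.feature[nd] >= 0) used[tr.feature[nd]] = 1;
    for (int f = 0; f < p; ++f) {
      if (!used[f]) continue;
      permuted.resize(m);
      for (int j = 0; j < m; ++j) permuted[j] = X(oob[j], f);
      for (int j = m - 1; j > 0; --j)
        std::swap(permuted[j], permuted[rng.randint(j + 1)]);
      int correct = 0;
      for (int j = 0; j < m; ++j)
        if (predict_case(tr, X, oob[j], f, permuted[j]) == y[oob[j]]) correct++;
      imp[f] += acc0 - static_cast<double>(correct) / m;
    }
  }
  if (trees_used > 0) imp = imp / trees_used;
  return imp;
}

// Case-case proximity: fraction of trees in which two cases share a terminal
// node (all cases, as in the classical forest imputer's rough default).
// [[Rcpp::export]]
NumericMatrix cpp_proximity(List trees, NumericMatrix X) {
  int n = X.nrow(), ntree = trees.size();
  NumericMatrix prox(n, n);
  std::vector<int> leaf(n);
  for (int t = 0; t < ntree; ++t) {
    Tree tr = tree_from_list(trees[t]);
    int nleaf = 0;
    for (int i = 0; i < n; ++i) {
      leaf[i] = leaf_of_case(tr, X, i);
      if (leaf[i] + 1 > nleaf) nleaf = leaf[i] + 1;
    }
    // bucket cases by leaf, then add within buckets
    std::vector<std::vector<int> > buckets(nleaf);
    for (int i = 0; i < n; ++i) buckets[leaf[i]].push_back(i);
    for (int b = 0; b < nleaf; ++b) {
      const std::vector<int>& cs = buckets[b];
      for (size_t a = 0; a < cs.size(); ++a)
        for (size_t c = 0; c < cs.size(); ++c)
          prox(cs[a], cs[c]) += 1.0;
    }
  }
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) prox(i, j) /= ntree;
  return prox;
}
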