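// C4.5-style binary-threshold tree induction on continuous features,
// error-based (confidence-factor) pruning, prediction and the LOOCV
// inner loop. Class encoding: 0 = "normal", 1 = "tumor"; ties at a node
// fall back to the parent's majority, and a root tie resolves to class 0
// (lexicographically first label).

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

struct Node {
  bool leaf;
  int feat;        // 0-based feature column; -1 at a leaf
  double thr;      // split threshold: <= goes left, > goes right
  int left, right; // 0-based node indices; -1 at a leaf
  int n0, n1;      // class counts of training samples reaching the node
  int cls;         // class assigned if this node were (or is) a leaf
};

const double kEps = 1e-12;

double entropy2(double c0, double c1) {
  double n = c0 + c1;
  if (n <= 0.0) return 0.0;
  double h = 0.0;
  if (c0 > 0.0) { double p = c0 / n; h -= p * std::log2(p); }
  if (c1 > 0.0) { double p = c1 / n; h -= p * std::log2(p); }
  return h;
}

struct SplitResult { bool found; double thr; double score; };

// Candidate thresholds are every distinct observed value except the
// maximum; the partition is {<= v} vs {> v}. First-encountered maximum
// (lowest threshold) wins ties, so induction is fully deterministic.
SplitResult best_split_vec(const std::vector<double>& v,
                           const std::vector<int>& y,
                           int min_leaf, bool gain_ratio, bool mdl) {
  int n = static_cast<int>(v.size());
  SplitResult best = {false, 0.0, 0.0};
  if (n < 2) return best;
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(),
                   [&](int a, int b) { return v[a] < v[b]; });
  int tot1 = 0;
  for (int i = 0; i < n; ++i) tot1 += y[i];
  int tot0 = n - tot1;
  double hparent = entropy2(tot0, tot1);
  // MDL correction for continuous thresholds (C4.5 release 8 / J48):
  // charge log2(#admissible thresholds)/n against the gain, so weak
  // splits chosen from many candidates are not rewarded.
  double penalty = 0.0;
  if (mdl) {
    int cand = 0, c1p = 0;
    for (int i = 0; i < n - 1; ++i) {
      c1p += y[ord[i]];
      if (v[ord[i]] == v[ord[i + 1]]) continue;
      int nl = i + 1;
      if (nl < min_leaf || n - nl < min_leaf) continue;
      ++cand;
    }
    if (cand == 0) return best;
    penalty = std::log2(static_cast<double>(cand)) / n;
  }
  int c1 = 0;
  for (int i = 0; i < n - 1; ++i) {
    c1 += y[ord[i]];
    if (v[ord[i]] == v[ord[i + 1]]) continue;
    int nl = i + 1, nr = n - nl;
    if (nl < min_leaf || nr < min_leaf) continue;
    int l1 = c1, l0 = nl - l1;
    int r1 = tot1 - l1, r0 = nr - r1;
    double gain = hparent -
      (nl * entropy2(l0, l1) + nr * entropy2(r0, r1)) / n - penalty;
    double score = gain;
    if (gain_ratio) {
      double si = entropy2(static_cast<double>(nl), static_cast<double>(nr));
      if (si <= 0.0) continue;
      score = gain / si;
    }
    if (score > kEps && (!best.found || score > best.score + kEps)) {
      best.found = true;
      best.thr = v[ord[i]];
      best.score = score;
    }
  }
  return best;
}

int grow_node(const NumericMatrix& X, const std::vector<int>& y,
              const std::vector<int>& idx, int parent_maj,
              int min_leaf, bool gain_ratio, bool mdl,
              std::vector<Node>& nodes) {
  int n = static_cast<int>(idx.size());
  int n1 = 0;
  for (int i : idx) n1 += y[i];
  int n0 = n - n1;
  int maj = (n1 > n0) ? 1 : ((n0 > n1) ? 0 : parent_maj);

  Node nd;
  nd.leaf = true; nd.feat = -1; nd.thr = NA_REAL;
  nd.left = -1; nd.right = -1;
  nd.n0 = n0; nd.n1 = n1; nd.cls = maj;

  if (n0 == 0 || n1 == 0 || n < 2 * min_leaf) {
    nodes.push_back(nd);
    return static_cast<int>(nodes.size()) - 1;
  }

  int nf = X.ncol();
  bool found = false;
  double bthr = 0.0, bscore = 0.0;
  int bfeat = -1;
  std::vector<double> v(n);
  std::vector<int> yy(n);
  for (int i = 0; i < n; ++i) yy[i] = y[idx[i]];
  for (int f = 0; f < nf; ++f) {
    for (int i = 0; i < n; ++i) v[i] = X(idx[i], f);
    SplitResult s = best_split_vec(v, yy, min_leaf, gain_ratio, mdl);
    if (s.found && (!found || s.score > bscore + kEps)) {
      found = true;
      bscore = s.score; bthr = s.thr; bfeat = f;
    }
  }
  if (!found) {
    nodes.push_back(nd);
    return static_cast<int>(nodes.size()) - 1;
  }

  nd.leaf = false; nd.feat = bfeat; nd.thr = bthr;
  nodes.push_back(nd);
  int self = static_cast<int>(nodes.size()) - 1;
  std::vector<int> li, ri;
  li.reserve(n); ri.reserve(n);
  for (int i : idx) {
    if (X(i, bfeat) <= bthr) li.push_back(i); else ri.push_back(i);
  }
  int l = grow_node(X, y, li, maj, min_leaf, gain_ratio, mdl, nodes);
  int r = grow_node(X, y, ri, maj, min_leaf, gain_ratio, mdl, nodes);
  nodes[self].left = l;
  nodes[self].right = r;
  return self;
}

// Upper confidence bound on the true error rate: largest p with
// P(X <= e | n, p) = cf, i.e. the (1-cf) quantile of Beta(e+1, n-e).
double ucf_bound(double e, double n, double cf) {
  if (e >= n) return 1.0;
  return R::qbeta(1.0 - cf, e + 1.0, n - e, 1, 0);
}

// Bottom-up subtree replacement; returns the (possibly pruned) subtree's
// summed pessimistic error estimate sum over leaves of n * ucf(e, n).
double prune_node(std::vector<Node>& nodes, int i, int parent_maj, double cf) {
  int n = nodes[i].n0 + nodes[i].n1;
  int maj = (nodes[i].n1 > nodes[i].n0) ? 1
            : ((nodes[i].n0 > nodes[i].n1) ? 0 : parent_maj);
  if (nodes[i].leaf) {
    int e = (nodes[i].cls == 1) ? nodes[i].n0 : nodes[i].n1;
    return n * ucf_bound(e, n, cf);
  }
  double sub = prune_node(nodes, nodes[i].left, maj, cf) +
               prune_node(nodes, nodes[i].right, maj, cf);
  int E = (maj == 1) ? nodes[i].n0 : nodes[i].n1;
  double leaf_est = n * ucf_bound(E, n, cf);
  if (leaf_est <= sub) {
    nodes[i].leaf = true;
    nodes[i].feat = -1; nodes[i].thr = NA_REAL;
    nodes[i].left = -1; nodes[i].right = -1;
    nodes[i].cls = maj;
    return leaf_est;
  }
  return sub;
}

// Compact the node vector after pruning (dead subtrees dropped),
// preserving preorder numbering from the root at index 0.
void compact(const std::vector<Node>& nodes, int i,
             std::vector<Node>& out, int& self) {
  out.push_back(nodes[i]);
  self = static_cast<int>(out.size()) - 1;
  if (!nodes[i].leaf) {
    int l, r;
    compact(nodes, nodes[i].left, out, l);
    compact(nodes, nodes[i].right, out, r);
    out[self].left = l;
    out[self].right = r;
  }
}

std::vector<Node> grow_tree(const NumericMatrix& X, const std::vector<int>& y,
                            int min_leaf, bool gain_ratio, bool mdl,
                            bool prune, double cf) {
  int n = X.nrow();
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::vector<Node> nodes;
  grow_node(X, y, idx, 0, min_leaf, gain_ratio, mdl, nodes);
  if (prune) prune_node(nodes, 0, 0, cf);
  std::vector<Node> out;
  int root;
  compact(nodes, 0, out, root);
  return out;
}

int descend(const std::vector<Node>& nodes, const NumericMatrix& X, int row) {
  int cur = 0;
  while (!nodes[cur].leaf) {
    cur = (X(row, nodes[cur].feat) <= nodes[cur].thr)
            ? nodes[cur].left : nodes[cur].right;
  }
  return nodes[cur].cls;
}

List nodes_to_list(const std::vector<Node>& nodes) {
  int m = static_cast<int>(nodes.size());
  LogicalVector leaf(m);
  IntegerVector feat(m), left(m), right(m), n0(m), n1(m), cls(m);
  NumericVector thr(m);
  for (int i = 0; i < m; ++i) {
    leaf[i] = nodes[i].leaf;
    feat[i] = nodes[i].leaf ? NA_INTEGER : nodes[i].feat + 1;
    thr[i] = nodes[i].leaf ? NA_REAL : nodes[i].thr;
    left[i] = nodes[i].leaf ? NA_INTEGER : nodes[i].left + 1;
    right[i] = nodes[i].leaf ? NA_INTEGER : nodes[i].right + 1;
    n0[i] = nodes[i].n0;
    n1[i] = nodes[i].n1;
    cls[i] = nodes[i].cls;
  }
  return List::create(_["leaf"] = leaf, _["feature"] = feat,
                      _["threshold"] = thr, _["left"] = left,
                      _["right"] = right, _["n0"] = n0, _["n1"] = n1,
                      _["class"] = cls);
}

} // namespace

// [[Rcpp::export]]
List cpp_grow(NumericMatrix X, IntegerVector y, int min_leaf,
              bool gain_ratio, bool mdl, bool prune, double cf) {
  std::vector<int> yv(y.begin(), y.end());
  std::vector<Node> nodes =
    grow_tree(X, yv, min_leaf, gain_ratio, mdl, prune, cf);
  return nodes_to_list(nodes);
}

// [[Rcpp::export]]
List cpp_best_split(NumericVector values, IntegerVector y,
                    int min_leaf, bool gain_ratio, bool mdl) {
  std::vector<double> v(values.begin(), values.end());
  std::vector<int> yy(y.begin(), y.end());
  SplitResult s = best_split_vec(v, yy, min_leaf, gain_ratio, mdl);
  return List::create(_["found"] = s.found, _["threshold"] = s.thr,
                      _["score"] = s.score);
}

// [[Rcpp::export]]
IntegerVector cpp_predict(LogicalVector leaf, IntegerVector feature,
                          NumericVector threshold, IntegerVector left,
                          IntegerVector right, IntegerVector cls,
                          NumericMatrix X) {
  int m = leaf.size(), n = X.nrow();
  std::vector<Node> nodes(m);
  for (int i = 0; i < m; ++i) {
    nodes[i].leaf = leaf[i];
    nodes[i].feat = leaf[i] ? -1 : feature[i] - 1;
    nodes[i].thr = leaf[i] ? 0.0 : threshold[i];
    nodes[i].left = leaf[i] ? -1 : left[i] - 1;
    nodes[i].right = leaf[i] ? -1 : right[i] - 1;
    nodes[i].cls = cls[i];
  }
  IntegerVector out(n);
  for (int r = 0; r < n; ++r) out[r] = descend(nodes, X, r);
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_loocv(NumericMatrix X, IntegerVector y, int min_leaf,
                        bool gain_ratio, bool mdl, bool prune, double cf) {
  int n = X.nrow();
  std::vector<int> yv(y.begin(), y.end());
  IntegerVector out(n);
  std::vector<int> idx;
  idx.reserve(n - 1);
  for (int h = 0; h < n; ++h) {
    idx.clear();
    for (int i = 0; i < n; ++i) if (i != h) idx.push_back(i);
    std::vector<Node> nodes;
    grow_node(X, yv, idx, 0, min_leaf, gain_ratio, mdl, nodes);
    if (prune) prune_node(nodes, 0, 0, cf);
    out[h] = descend(nodes, X, h);
  }
  return out;
}

// [[Rcpp::export]]
double cpp_ucf(double e, double n, double cf) {
  return ucf_bound(e, n, cf);
}
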