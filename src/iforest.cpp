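// Isolation forest (Liu, Ting & Zhou 2008): trees are grown on subsamples of
// size psi with uniformly random axis-parallel splits; the anomaly score of a
// point is 2^(-E[h]/c(psi)) where E[h] is its mean path length across trees
// and c(m) the average unsuccessful-search depth of a BST of m nodes.
// Only the mean adjusted path lengths are computed here; the score transform
// and thresholding live in R.
#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Node {
  int feature;      // -1 for leaf
  double split;
  int left, right;  // child node ids
  double adj;       // leaf: c(size) path-length adjustment
};

double avg_bst_depth(int m) {
  if (m <= 1) return 0.0;
  const double euler = 0.5772156649015329;
  double h = std::log((double)(m - 1)) + euler;
  return 2.0 * h - 2.0 * (double)(m - 1) / (double) m;
}

class TreeBuilder {
public:
  TreeBuilder(const NumericMatrix &X, std::mt19937 &rng, int depth_limit)
    : X_(X), rng_(rng), depth_limit_(depth_limit) {}

  std::vector<Node> nodes;

  int build(std::vector<int> &idx, int depth) {
    int p = X_.ncol();
    Node nd;
    if ((int) idx.size() <= 1 || depth >= depth_limit_) {
      nd.feature = -1; nd.split = 0.0; nd.left = nd.right = -1;
      nd.adj = avg_bst_depth((int) idx.size());
      nodes.push_back(nd);
      return (int) nodes.size() - 1;
    }
    // candidate features: those with a non-degenerate range on idx
    std::vector<int> feats;
    std::vector<double> lo(p), hi(p);
    for (int j = 0; j < p; ++j) {
      double mn = R_PosInf, mx = R_NegInf;
      for (int i : idx) {
        double v = X_(i, j);
        if (v < mn) mn = v;
        if (v > mx) mx = v;
      }
      lo[j] = mn; hi[j] = mx;
      if (mx > mn) feats.push_back(j);
    }
    if (feats.empty()) {  // all points identical
      nd.feature = -1; nd.split = 0.0; nd.left = nd.right = -1;
      nd.adj = avg_bst_depth((int) idx.size());
      nodes.push_back(nd);
      return (int) nodes.size() - 1;
    }
    std::uniform_int_distribution<int> fpick(0, (int) feats.size() - 1);
    int f = feats[fpick(rng_)];
    std::uniform_real_distribution<double> spick(lo[f], hi[f]);
    double s = spick(rng_);
    std::vector<int> li, ri;
    for (int i : idx) (X_(i, f) < s ? li : ri).push_back(i);
    if (li.empty() || ri.empty()) {
      // split fell outside the empirical support; treat as leaf
      nd.feature = -1; nd.split = 0.0; nd.left = nd.right = -1;
      nd.adj = avg_bst_depth((int) idx.size());
      nodes.push_back(nd);
      return (int) nodes.size() - 1;
    }
    nd.feature = f; nd.split = s; nd.adj = 0.0;
    nodes.push_back(nd);
    int self = (int) nodes.size() - 1;
    int l = build(li, depth + 1);
    int r = build(ri, depth + 1);
    nodes[self].left = l;
    nodes[self].right = r;
    return self;
  }

private:
  const NumericMatrix &X_;
  std::mt19937 &rng_;
  int depth_limit_;
};

} // namespace

// Mean adjusted isolation depth per row of X.
// psi: subsample size per tree; depth_limit < 0 means ceil(log2(psi)).
// [[Rcpp::export]]
NumericVector iforest_depths(NumericMatrix X, int ntrees, int psi, int seed,
                             int depth_limit = -1) {
  int n = X.nrow();
  NumericVector out(n);
  if (n == 0) return out;
  if (psi > n) psi = n;
  if (psi < 2) psi = n >= 2 ? 2 : n;
  int dl = depth_limit;
  if (dl < 0) dl = (int) std::ceil(std::log2((double) std::max(psi, 2)));
  std::mt19937 rng((uint32_t) seed);
  std::vector<double> acc(n, 0.0);
  std::vector<int> perm(n);
  for (int t = 0; t < ntrees; ++t) {
    // draw subsample without replacement (partial Fisher-Yates)
    for (int i = 0; i < n; ++i) perm[i] = i;
    std::vector<int> idx(psi);
    for (int i = 0; i < psi; ++i) {
      std::uniform_int_distribution<int> pick(i, n - 1);
      int j = pick(rng);
      std::swap(perm[i], perm[j]);
      idx[i] = perm[i];
    }
    TreeBuilder tb(X, rng, dl);
    int root = tb.build(idx, 0);
    // score every point through this tree
    for (int i = 0; i < n; ++i) {
      int node = root;
      double depth = 0.0;
      while (tb.nodes[node].feature >= 0) {
        node = (X(i, tb.nodes[node].feature) < tb.nodes[node].split)
                 ? tb.nodes[node].left : tb.nodes[node].right;
        depth += 1.0;
      }
      acc[i] += depth + tb.nodes[node].adj;
    }
  }
  for (int i = 0; i < n; ++i) out[i] = acc[i] / (double) ntrees;
  return out;
}

// c(m) normalizer exposed for the score transform in R.
// [[Rcpp::export]]
double iforest_cnorm(int m) {
  return avg_bst_depth(m);
}
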