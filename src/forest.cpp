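#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Small classification random forest: bootstrap samples, Gini splits over
// `mtry` randomly drawn candidate features per node, nodes terminal when pure
// or at/below `min_node_size` bootstrap observations. Impurity importance is
// the total Gini decrease accumulated per feature; a feature counts as used
// by the model iff its importance is > 0.
//
// Split search works on per-feature value ranks computed once per fit: the
// node's rows are scattered into rank buckets and one sequential scan over
// the ranks finds the best threshold, so nothing is sorted per node.
// Randomness comes from R's RNG, so results follow set.seed().

namespace {

struct Node {
  int feature;      // -1 for leaf
  double threshold; // split: x <= threshold goes left
  int left, right;
  int pred;
};

struct Forest {
  const double* x; // column-major n x p
  const int* y;
  int n, p, mtry, min_node_size;
  std::vector<int> rank;         // p x n: rank[j*n + row], distinct per row
  std::vector<double> sorted;    // p x n: value at each rank
  std::vector<double> importance;
  std::vector<Node> nodes;
  std::vector<int> cand;
  std::vector<int> cnt;          // bootstrap multiplicity of each row
  std::vector<int> abuf, bbuf;   // rank-bucket scatter buffers
  std::vector<double> inv;       // inv[k] = 1.0 / k for the count range

  Forest(const NumericMatrix& xm, const IntegerVector& yv, int mtry_, int mns)
      : x(xm.begin()), y(yv.begin()), n(xm.nrow()), p(xm.ncol()),
        mtry(mtry_), min_node_size(mns), rank((size_t)p * n),
        sorted((size_t)p * n), importance(p, 0.0), cand(p), cnt(n),
        abuf(n, 0), bbuf(n, 0), inv(n + 1, 0.0) {
    for (int k = 1; k <= n; ++k) inv[k] = 1.0 / k;
    std::vector<int> ord(n);
    for (int j = 0; j < p; ++j) {
      const double* col = x + (size_t)j * n;
      for (int i = 0; i < n; ++i) ord[i] = i;
      std::stable_sort(ord.begin(), ord.end(),
                       [col](int a, int b) { return col[a] < col[b]; });
      for (int s = 0; s < n; ++s) {
        rank[(size_t)j * n + ord[s]] = s;
        sorted[(size_t)j * n + s] = col[ord[s]];
      }
      cand[j] = j;
    }
  }

  // rows: bootstrap-present rows of this node; nn/n1 weighted by cnt
  int build(std::vector<int>& rows, int nn, int n1) {
    const int majority = (2 * n1 > nn) ? 1 : 0;
    if (n1 == 0 || n1 == nn || nn <= min_node_size) {
      nodes.push_back({-1, 0.0, -1, -1, majority});
      return (int)nodes.size() - 1;
    }
    // Gini decrease = 2 (l1^2/l + r1^2/r - n1^2/nn) with integer counts
    // l, l1, r, r1; the reciprocal table removes all divisions.
    const double base = (double)n1 * n1 * inv[nn];
    int best_feat = -1;
    double best_thr = 0.0, best_score = base + 0.5e-12;
    for (int t = 0; t < mtry; ++t) {
      int r = t + (int)(unif_rand() * (p - t));
      if (r >= p) r = p - 1;
      std::swap(cand[t], cand[r]);
      const int j = cand[t];
      const int* rk = rank.data() + (size_t)j * n;
      const double* vals = sorted.data() + (size_t)j * n;
      for (int row : rows) {
        const int s = rk[row];
        abuf[s] = cnt[row];
        bbuf[s] = cnt[row] * y[row];
      }
      int ln = 0, ln1 = 0;
      double prev = 0.0;
      bool have_prev = false;
      for (int s = 0; s < n; ++s) {
        const int c = abuf[s];
        if (c == 0) continue;
        const double v = vals[s];
        if (have_prev && v > prev && ln < nn) {
          const double score = (double)ln1 * ln1 * inv[ln] +
                               (double)(n1 - ln1) * (n1 - ln1) * inv[nn - ln];
          if (score > best_score) {
            best_score = score;
            best_feat = j;
            best_thr = (prev + v) / 2.0;
          }
        }
        ln += c;
        ln1 += bbuf[s];
        prev = v;
        have_prev = true;
      }
      for (int row : rows) { // reset only the touched buckets
        abuf[rk[row]] = 0;
        bbuf[rk[row]] = 0;
      }
    }
    if (best_feat < 0) { // no admissible split among the candidates
      nodes.push_back({-1, 0.0, -1, -1, majority});
      return (int)nodes.size() - 1;
    }
    importance[best_feat] += 2.0 * (best_score - base);
    std::vector<int> lrows, rrows;
    lrows.reserve(rows.size());
    rrows.reserve(rows.size());
    int lnn = 0, ln1 = 0, rnn = 0, rn1 = 0;
    const double* col = x + (size_t)best_feat * n;
    for (int row : rows) {
      if (col[row] <= best_thr) {
        lrows.push_back(row);
        lnn += cnt[row];
        ln1 += cnt[row] * y[row];
      } else {
        rrows.push_back(row);
        rnn += cnt[row];
        rn1 += cnt[row] * y[row];
      }
    }
    rows.clear();
    rows.shrink_to_fit();
    const int me = (int)nodes.size();
    nodes.push_back({best_feat, best_thr, -1, -1, majority});
    const int l = build(lrows, lnn, ln1);
    const int r = build(rrows, rnn, rn1);
    nodes[me].left = l;
    nodes[me].right = r;
    return me;
  }

  int predict(int root, const double* xt, int ntest, int row) const {
    int cur = root;
    while (nodes[cur].feature >= 0) {
      const double v = xt[(size_t)nodes[cur].feature * ntest + row];
      cur = (v <= nodes[cur].threshold) ? nodes[cur].left : nodes[cur].right;
    }
    return nodes[cur].pred;
  }
};

} // namespace

// Fits the forest and immediately scores `xtest`, so no tree store has to
// cross the R boundary. Returns the per-feature impurity importance and the
// fraction of trees voting class 1 for each test row.
// [[Rcpp::export(name = ".forest_fit_predict")]]
List forest_fit_predict(NumericMatrix xtrain, IntegerVector y,
                        NumericMatrix xtest, int num_trees, int mtry,
                        int min_node_size) {
  const int n = xtrain.nrow();
  const int ntest = xtest.nrow();
  Forest forest(xtrain, y, mtry, min_node_size);
  std::vector<double> votes(ntest, 0.0);
  RNGScope scope;
  for (int t = 0; t < num_trees; ++t) {
    std::fill(forest.cnt.begin(), forest.cnt.end(), 0);
    int n1 = 0;
    for (int i = 0; i < n; ++i) {
      int r = (int)(unif_rand() * n);
      if (r >= n) r = n - 1;
      ++forest.cnt[r];
      n1 += y[r];
    }
    std::vector<int> rows;
    rows.reserve(n);
    for (int i = 0; i < n; ++i) {
      if (forest.cnt[i] > 0) rows.push_back(i);
    }
    forest.nodes.clear();
    const int root = forest.build(rows, n, n1);
    for (int i = 0; i < ntest; ++i) {
      votes[i] += forest.predict(root, xtest.begin(), ntest, i);
    }
  }
  for (int i = 0; i < ntest; ++i) votes[i] /= num_trees;
  return List::create(
    _["importance"] =
        NumericVector(forest.importance.begin(), forest.importance.end()),
    _["votes"] = NumericVector(votes.begin(), votes.end())
  );
}
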