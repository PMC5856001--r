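// Gini-split classification random forest with bootstrap resampling,
// per-node feature subsampling (mtry) and out-of-bag permutation variable
// importance (mean decrease in OOB accuracy), i.e. the contract of the
// ranger defaults used for DSB prediction. Randomness flows through R's
// RNG so results are reproducible under set.seed().
#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

namespace {

struct Tree {
  std::vector<int> var, left, right;
  std::vector<double> split, pred;
};

int unif_index(int n) {
  int k = (int)(R::unif_rand() * n);
  return k >= n ? n - 1 : k;
}

int make_node(Tree &t) {
  t.var.push_back(-1);
  t.split.push_back(0.0);
  t.left.push_back(-1);
  t.right.push_back(-1);
  t.pred.push_back(0.0);
  return (int)t.var.size() - 1;
}

void split_node(Tree &t, int node, const NumericMatrix &X,
                const IntegerVector &y, std::vector<int> &idx, int lo, int hi,
                int mtry, int min_node, std::vector<int> &vars_buf) {
  const int n = hi - lo;
  int n1 = 0;
  for (int i = lo; i < hi; ++i) n1 += y[idx[i]];
  t.pred[node] = (double)n1 / n;
  if (n1 == 0 || n1 == n || n < 2 || n <= min_node) return;

  const int p = X.ncol();
  for (int j = 0; j < p; ++j) vars_buf[j] = j;
  // partial Fisher-Yates draws mtry distinct features
  int best_var = -1;
  double best_split = 0.0, best_score = -1.0;
  std::vector<std::pair<double, int>> vals(n);
  for (int m = 0; m < mtry; ++m) {
    int r = m + unif_index(p - m);
    std::swap(vars_buf[m], vars_buf[r]);
    int v = vars_buf[m];
    for (int i = 0; i < n; ++i) {
      vals[i].first = X(idx[lo + i], v);
      vals[i].second = y[idx[lo + i]];
    }
    std::sort(vals.begin(), vals.end());
    int n1L = 0;
    for (int i = 0; i < n - 1; ++i) {
      n1L += vals[i].second;
      if (vals[i + 1].first <= vals[i].first) continue;  // tie, no cut here
      const int nL = i + 1, nR = n - nL;
      const int n1R = n1 - n1L;
      const double score =
          ((double)n1L * n1L + (double)(nL - n1L) * (nL - n1L)) / nL +
          ((double)n1R * n1R + (double)(nR - n1R) * (nR - n1R)) / nR;
      if (score > best_score) {
        best_score = score;
        best_var = v;
        best_split = (vals[i].first + vals[i + 1].first) / 2.0;
      }
    }
  }
  if (best_var < 0) return;  // constant within node on all sampled features

  int mid = lo;
  for (int i = lo; i < hi; ++i) {
    if (X(idx[i], best_var) <= best_split) std::swap(idx[i], idx[mid++]);
  }
  if (mid == lo || mid == hi) return;  // numerical degeneracy guard
  t.var[node] = best_var;
  t.split[node] = best_split;
  int l = make_node(t), r = make_node(t);
  t.left[node] = l;
  t.right[node] = r;
  split_node(t, l, X, y, idx, lo, mid, mtry, min_node, vars_buf);
  split_node(t, r, X, y, idx, mid, hi, mtry, min_node, vars_buf);
}

// tree vote for one sample; perm_var/perm_val substitute a permuted value
int tree_vote(const Tree &t, const NumericMatrix &X, int row, int perm_var,
              double perm_val) {
  int node = 0;
  while (t.var[node] >= 0) {
    double x = (t.var[node] == perm_var) ? perm_val : X(row, t.var[node]);
    node = (x <= t.split[node]) ? t.left[node] : t.right[node];
  }
  return t.pred[node] >= 0.5 ? 1 : 0;
}

double oob_accuracy(const Tree &t, const NumericMatrix &X,
                    const IntegerVector &y, const std::vector<int> &oob,
                    int perm_var, const std::vector<int> &perm) {
  int correct = 0;
  for (size_t i = 0; i < oob.size(); ++i) {
    double pv = 0.0;
    if (perm_var >= 0) pv = X(oob[perm[i]], perm_var);
    correct += (tree_vote(t, X, oob[i], perm_var, pv) == y[oob[i]]);
  }
  return (double)correct / oob.size();
}

}  // namespace

// [[Rcpp::export]]
List forest_train_cpp(NumericMatrix X, IntegerVector y, int num_trees,
                      int mtry, int min_node_size, bool importance) {
  const int n = X.nrow(), p = X.ncol();
  std::vector<Tree> forest(num_trees);
  std::vector<double> vi(p, 0.0);
  std::vector<int> oob_vote1(n, 0), oob_cnt(n, 0);
  int vi_trees = 0;

  std::vector<int> vars_buf(p), perm;
  for (int b = 0; b < num_trees; ++b) {
    std::vector<char> inbag(n, 0);
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) {
      int r = unif_index(n);
      idx[i] = r;
      inbag[r] = 1;
    }
    Tree &t = forest[b];
    make_node(t);
    split_node(t, 0, X, y, idx, 0, n, mtry, min_node_size, vars_buf);

    std::vector<int> oob;
    for (int i = 0; i < n; ++i)
      if (!inbag[i]) oob.push_back(i);
    if (oob.empty()) continue;
    for (size_t i = 0; i < oob.size(); ++i) {
      oob_vote1[oob[i]] += tree_vote(t, X, oob[i], -1, 0.0);
      oob_cnt[oob[i]] += 1;
    }
    if (importance) {
      perm.resize(oob.size());
      for (size_t i = 0; i < oob.size(); ++i) perm[i] = (int)i;
      double acc = oob_accuracy(t, X, y, oob, -1, perm);
      for (int v = 0; v < p; ++v) {
        for (int i = (int)perm.size() - 1; i > 0; --i) {
          std::swap(perm[i], perm[unif_index(i + 1)]);
        }
        vi[v] += acc - oob_accuracy(t, X, y, oob, v, perm);
      }
      ++vi_trees;
    }
  }

  List trees(num_trees);
  for (int b = 0; b < num_trees; ++b) {
    trees[b] = List::create(
        _["var"] = wrap(forest[b].var), _["split"] = wrap(forest[b].split),
        _["left"] = wrap(forest[b].left), _["right"] = wrap(forest[b].right),
        _["pred"] = wrap(forest[b].pred));
  }
  NumericVector imp(p);
  for (int v = 0; v < p; ++v) imp[v] = vi_trees ? vi[v] / vi_trees : NA_REAL;

  // OOB vote-fraction score and error
  NumericVector oob_score(n);
  int err = 0, scored = 0;
  for (int i = 0; i < n; ++i) {
    if (oob_cnt[i] == 0) {
      oob_score[i] = NA_REAL;
      continue;
    }
    oob_score[i] = (double)oob_vote1[i] / oob_cnt[i];
    err += ((oob_score[i] >= 0.5 ? 1 : 0) != y[i]);
    ++scored;
  }
  return List::create(_["trees"] = trees, _["importance"] = imp,
                      _["oob_score"] = oob_score,
                      _["oob_error"] =
                          scored ? (double)err / scored : NA_REAL);
}

// [[Rcpp::export]]
NumericVector forest_predict_cpp(List trees, NumericMatrix X) {
  const int n = X.nrow(), ntree = trees.size();
  std::vector<Tree> forest(ntree);
  for (int b = 0; b < ntree; ++b) {
    List tl = trees[b];
    forest[b].var = as<std::vector<int>>(tl["var"]);
    forest[b].split = as<std::vector<double>>(tl["split"]);
    forest[b].left = as<std::vector<int>>(tl["left"]);
    forest[b].right = as<std::vector<int>>(tl["right"]);
    forest[b].pred = as<std::vector<double>>(tl["pred"]);
  }
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    int votes = 0;
    for (int b = 0; b < ntree; ++b)
      votes += tree_vote(forest[b], X, i, -1, 0.0);
    out[i] = (double)votes / ntree;
  }
  return out;
}
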