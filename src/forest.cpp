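#include <Rcpp.h>
#include "rbf_rng.h"
#include "bitpack.h"
using namespace Rcpp;

// task codes
static const int TASK_REG = 0;
static const int TASK_CLS = 1;

// Split score on a node (indices are a bootstrap multiset):
//   regression    -> between-group sum of squares of the targets
//   classification-> Gini decrease (targets are 0/1 doubles)
// Both are 0 when the bit does not separate the node. Candidates are scanned
// in ascending bit order with a strict ">" so the lowest index wins ties.
struct SplitScan {
  int bit;       // -1 = none
  double score;
};

static SplitScan best_split_core(const uint64_t *words, int wpc,
                                 const double *targets, const int *idx,
                                 int n_node, const int *cand, int n_cand,
                                 int task) {
  double nt = 0, st = 0;
  for (int t = 0; t < n_node; ++t) { nt += 1; st += targets[idx[t]]; }
  SplitScan out; out.bit = -1; out.score = 0.0;
  for (int c = 0; c < n_cand; ++c) {
    const int j = cand[c];
    const uint64_t *col = words + (size_t)j * wpc;
    double n1 = 0, s1 = 0;
    for (int t = 0; t < n_node; ++t) {
      const int i = idx[t];
      if (rbf_get_bit(col, i)) { n1 += 1; s1 += targets[i]; }
    }
    double n0 = nt - n1, s0 = st - s1;
    if (n0 == 0 || n1 == 0) continue;
    double score;
    if (task == TASK_REG) {
      double m0 = s0 / n0, m1 = s1 / n1, gm = st / nt;
      score = n0 * (m0 - gm) * (m0 - gm) + n1 * (m1 - gm) * (m1 - gm);
    } else {
      double p = st / nt, p0 = s0 / n0, p1 = s1 / n1;
      double gp = 2.0 * p * (1.0 - p);
      score = gp - (n0 * (2.0 * p0 * (1.0 - p0)) +
                    n1 * (2.0 * p1 * (1.0 - p1))) / nt;
    }
    if (score > out.score) { out.score = score; out.bit = j; }
  }
  return out;
}

struct TreeArrays {
  std::vector<int> split_bit, left, right;
  std::vector<double> value;
};

static int grow_node(const uint64_t *words, int wpc, const double *targets,
                     std::vector<int> &idx, int lo, int hi,
                     const int *cand, int n_cand, int min_node, int task,
                     TreeArrays &tr) {
  const int n_node = hi - lo;
  double st = 0;
  bool pure = true;
  const double t0 = targets[idx[lo]];
  for (int t = lo; t < hi; ++t) {
    st += targets[idx[t]];
    if (targets[idx[t]] != t0) pure = false;
  }
  const int me = (int)tr.split_bit.size();
  tr.split_bit.push_back(-1);
  tr.left.push_back(-1);
  tr.right.push_back(-1);
  tr.value.push_back(st / n_node);
  if (pure || n_node < 2 * min_node) return me;
  SplitScan s = best_split_core(words, wpc, targets, &idx[lo], n_node, cand,
                                n_cand, task);
  if (s.bit < 0) return me;
  // stable partition: bit-0 members first, original order preserved
  std::vector<int> zeros, ones;
  zeros.reserve(n_node); ones.reserve(n_node);
  const uint64_t *col = words + (size_t)s.bit * wpc;
  for (int t = lo; t < hi; ++t) {
    if (rbf_get_bit(col, idx[t])) ones.push_back(idx[t]);
    else zeros.push_back(idx[t]);
  }
  int mid = lo + (int)zeros.size();
  std::copy(zeros.begin(), zeros.end(), idx.begin() + lo);
  std::copy(ones.begin(), ones.end(), idx.begin() + mid);
  tr.split_bit[me] = s.bit;
  int l = grow_node(words, wpc, targets, idx, lo, mid, cand, n_cand,
                    min_node, task, tr);
  int r = grow_node(words, wpc, targets, idx, mid, hi, cand, n_cand,
                    min_node, task, tr);
  tr.left[me] = l;
  tr.right[me] = r;
  return me;
}

// [[Rcpp::export]]
List cpp_best_split(RawVector words, int n_samples, int n_bits,
                    NumericVector targets, IntegerVector node_idx,
                    IntegerVector cand_bits, int task) {
  if (node_idx.size() == 0) stop("node_idx must be nonempty");
  const int wpc = rbf_words_per_col(n_samples);
  for (R_xlen_t t = 0; t < node_idx.size(); ++t)
    if (node_idx[t] < 0 || node_idx[t] >= n_samples)
      stop("node index out of range");
  for (R_xlen_t t = 0; t < cand_bits.size(); ++t)
    if (cand_bits[t] < 0 || cand_bits[t] >= n_bits)
      stop("candidate bit index out of range");
  SplitScan s = best_split_core((const uint64_t *)RAW(words), wpc,
                                REAL(targets), INTEGER(node_idx),
                                node_idx.size(), INTEGER(cand_bits),
                                cand_bits.size(), task);
  return List::create(_["bit"] = s.bit, _["score"] = s.score);
}

// [[Rcpp::export]]
List cpp_grow_tree(RawVector words, int n_samples, int n_bits,
                   NumericVector targets, IntegerVector sample_idx,
                   IntegerVector cand_bits, int min_node, int task) {
  if (targets.size() != n_samples) stop("targets must have length n_samples");
  if (sample_idx.size() == 0) stop("empty bootstrap sample");
  const int wpc = rbf_words_per_col(n_samples);
  std::vector<int> idx(sample_idx.begin(), sample_idx.end());
  for (size_t t = 0; t < idx.size(); ++t)
    if (idx[t] < 0 || idx[t] >= n_samples) stop("sample index out of range");
  TreeArrays tr;
  grow_node((const uint64_t *)RAW(words), wpc, REAL(targets), idx, 0,
            (int)idx.size(), INTEGER(cand_bits), cand_bits.size(), min_node,
            task, tr);
  return List::create(_["split_bit"] = IntegerVector(tr.split_bit.begin(),
                                                     tr.split_bit.end()),
                      _["left"] = IntegerVector(tr.left.begin(),
                                                tr.left.end()),
                      _["right"] = IntegerVector(tr.right.begin(),
                                                 tr.right.end()),
                      _["value"] = NumericVector(tr.value.begin(),
                                                 tr.value.end()));
}

// Bootstrap draws for tree `tree_index` (0-based): first the sample indices,
// then the bit indices, from the tree's own derived substream.
// [[Rcpp::export]]
List cpp_forest_draws(double seed, int tree_index, int n_samples, int n_draw,
                      int n_bits_total, int bits_draw) {
  Xoshiro256 rng(rbf_derive_seed((uint64_t)seed, (uint64_t)tree_index));
  IntegerVector si(n_draw), bi(bits_draw);
  for (int t = 0; t < n_draw; ++t) si[t] = rng.unif_int(n_samples);
  for (int t = 0; t < bits_draw; ++t) bi[t] = rng.unif_int(n_bits_total);
  return List::create(_["sample_idx"] = si, _["bit_idx"] = bi);
}

// [[Rcpp::export]]
NumericVector cpp_predict_tree(List tree, RawVector words, int n_samples,
                               int n_bits) {
  IntegerVector split = tree["split_bit"], left = tree["left"],
                right = tree["right"];
  NumericVector value = tree["value"];
  const int wpc = rbf_words_per_col(n_samples);
  const uint64_t *w = (const uint64_t *)RAW(words);
  NumericVector out(n_samples);
  for (int i = 0; i < n_samples; ++i) {
    int node = 0;
    while (split[node] >= 0) {
      if (split[node] >= n_bits) stop("tree refers to a bit outside the pool");
      node = rbf_get_bit(w + (size_t)split[node] * wpc, i) ? right[node]
                                                           : left[node];
    }
    out[i] = value[node];
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_predict_forest(List trees, RawVector words, int n_samples,
                                 int n_bits) {
  const int T = trees.size();
  if (T == 0) stop("empty forest");
  const int wpc = rbf_words_per_col(n_samples);
  const uint64_t *w = (const uint64_t *)RAW(words);
  NumericVector out(n_samples);
  for (int tix = 0; tix < T; ++tix) {
    List tree = trees[tix];
    IntegerVector split = tree["split_bit"], left = tree["left"],
                  right = tree["right"];
    NumericVector value = tree["value"];
    for (int i = 0; i < n_samples; ++i) {
      int node = 0;
      while (split[node] >= 0) {
        if (split[node] >= n_bits)
          stop("tree refers to a bit outside the pool");
        node = rbf_get_bit(w + (size_t)split[node] * wpc, i) ? right[node]
                                                             : left[node];
      }
      out[i] += value[node];
    }
  }
  for (int i = 0; i < n_samples; ++i) out[i] /= T;
  return out;
}
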