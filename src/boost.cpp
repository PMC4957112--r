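#include <Rcpp.h>
#include "networks.h"
#include "pool_io.h"
#include "bitpack.h"
using namespace Rcpp;

// Between-group sum of squares of `res` split by `bits`:
//   n0*(m0 - m)^2 + n1*(m1 - m)^2, 0 if either group is empty.
// Arithmetic order mirrors the R explained_variance() so the argmax oracle
// test compares identical doubles.
static inline double between_group_ss(const double *res, const uint8_t *bits,
                                      int n) {
  double n0 = 0, s0 = 0, n1 = 0, s1 = 0;
  for (int i = 0; i < n; ++i) {
    if (bits[i]) { n1 += 1; s1 += res[i]; }
    else         { n0 += 1; s0 += res[i]; }
  }
  if (n0 == 0 || n1 == 0) return 0.0;
  double m0 = s0 / n0, m1 = s1 / n1, gm = (s0 + s1) / n;
  return n0 * (m0 - gm) * (m0 - gm) + n1 * (m1 - gm) * (m1 - gm);
}

// One boosting chain: residual starts at y; each of S steps scans C fresh
// candidate networks, keeps the strict-max between-group-SS candidate
// (first encountered wins ties; if all score 0 the first candidate is kept
// and the residual is left unchanged), then subtracts the groupwise means.
static void run_chain_core(const double *y, const double *Xp, int n, int nf,
                           int S, int C, int t1, int t2, uint64_t chain_seed,
                           std::vector<NetBuf> &nets_out,
                           std::vector<uint8_t> &bits_out, // n * S
                           double &final_sse, List *trace) {
  Xoshiro256 rng(chain_seed);
  std::vector<double> res(y, y + n);
  std::vector<uint8_t> cand(n), best(n), first(n);
  NetBuf cand_net, best_net, first_net;
  nets_out.resize(S);
  bits_out.assign((size_t)n * S, 0);
  for (int step = 0; step < S; ++step) {
    double max_var = 0.0;
    int best_idx = -1;
    IntegerMatrix trace_bits;
    NumericVector trace_var;
    if (trace) {
      trace_bits = IntegerMatrix(n, C);
      trace_var = NumericVector(C);
    }
    for (int c = 0; c < C; ++c) {
      rbf_sample_and_eval(cand_net, Xp, n, nf, t1, t2, rng, &cand[0]);
      double v = between_group_ss(&res[0], &cand[0], n);
      if (trace) {
        for (int i = 0; i < n; ++i) trace_bits(i, c) = cand[i];
        trace_var[c] = v;
      }
      if (c == 0) { first_net = cand_net; first = cand; }
      if (v > max_var) {
        max_var = v;
        best_idx = c;
        best_net = cand_net;
        best = cand;
      }
    }
    bool degenerate = (best_idx < 0);
    if (degenerate) { best_net = first_net; best = first; best_idx = 0; }
    nets_out[step] = best_net;
    std::copy(best.begin(), best.end(), bits_out.begin() + (size_t)n * step);
    if (!degenerate) {
      double n0 = 0, s0 = 0, n1 = 0, s1 = 0;
      for (int i = 0; i < n; ++i) {
        if (best[i]) { n1 += 1; s1 += res[i]; }
        else         { n0 += 1; s0 += res[i]; }
      }
      double m0 = (n0 > 0) ? s0 / n0 : 0.0;
      double m1 = (n1 > 0) ? s1 / n1 : 0.0;
      for (int i = 0; i < n; ++i) res[i] -= best[i] ? m1 : m0;
    }
    if (trace)
      (*trace)[step] = List::create(_["cand_bits"] = trace_bits,
                                    _["var"] = trace_var,
                                    _["chosen"] = best_idx + 1,
                                    _["degenerate"] = degenerate);
  }
  final_sse = 0.0;
  for (int i = 0; i < n; ++i) final_sse += res[i] * res[i];
}

// [[Rcpp::export]]
List cpp_run_chain(NumericVector y, NumericMatrix X, int S, int C, int twist1,
                   int twist2, double seed, double stream, bool trace) {
  const int n = X.nrow(), nf = X.ncol();
  if (y.size() != n) stop("y must have one value per row of X");
  if (n < 2) stop("need at least 2 samples");
  if (twist1 < 1 || twist1 > nf)
    stop("twist1 must be between 1 and the number of features");
  std::vector<NetBuf> nets;
  std::vector<uint8_t> bits;
  double sse = 0;
  List tr(trace ? S : 0);
  run_chain_core(REAL(y), REAL(X), n, nf, S, C, twist1, twist2,
                 rbf_derive_seed((uint64_t)seed, (uint64_t)stream), nets,
                 bits, sse, trace ? &tr : (List *)0);
  IntegerMatrix train_bits(n, S);
  for (int s = 0; s < S; ++s)
    for (int i = 0; i < n; ++i) train_bits(i, s) = bits[(size_t)n * s + i];
  List out = List::create(_["pool"] = rbf_nets_to_list(nets, twist1, twist2),
                          _["train_bits"] = train_bits,
                          _["final_sse"] = sse);
  if (trace) out["trace"] = tr;
  return out;
}

// [[Rcpp::export]]
List cpp_build_pool(NumericVector y, NumericMatrix X, int B, int S, int C,
                    int twist1, int twist2, double seed) {
  const int n = X.nrow(), nf = X.ncol();
  if (y.size() != n) stop("y must have one value per row of X");
  if (n < 2) stop("need at least 2 samples");
  if (twist1 < 1 || twist1 > nf)
    stop("twist1 must be between 1 and the number of features");
  const int P = B * S;
  const int wpc = rbf_words_per_col(n);
  std::vector<NetBuf> all((size_t)P);
  RawVector packed((R_xlen_t)P * wpc * 8);
  uint64_t *words = (uint64_t *)RAW(packed);
  NumericVector sse(B);
  std::vector<NetBuf> nets;
  std::vector<uint8_t> bits;
  for (int b = 0; b < B; ++b) {
    double chain_sse = 0;
    run_chain_core(REAL(y), REAL(X), n, nf, S, C, twist1, twist2,
                   rbf_derive_seed((uint64_t)seed, (uint64_t)b), nets, bits,
                   chain_sse, (List *)0);
    sse[b] = chain_sse;
    for (int s = 0; s < S; ++s) {
      all[(size_t)b * S + s] = nets[s];
      rbf_pack_column(&bits[(size_t)n * s], n,
                      words + ((size_t)b * S + s) * wpc);
    }
  }
  return List::create(_["pool"] = rbf_nets_to_list(all, twist1, twist2),
                      _["train_words"] = packed, _["n_samples"] = n,
                      _["chain_sse"] = sse);
}
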