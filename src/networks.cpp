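#include <Rcpp.h>
#include "networks.h"
#include "pool_io.h"
#include "bitpack.h"
using namespace Rcpp;

// [[Rcpp::export]]
double cpp_mix_seed(double seed, double stream) {
  // 53-bit derived seed, exactly representable as a double
  return (double)(rbf_derive_seed((uint64_t)seed, (uint64_t)stream) >> 11);
}

static NetBuf net_from_list(const List &pool, int p) {
  IntegerMatrix feat = pool["feat"];
  NumericMatrix wh = pool["w_hidden"], th = pool["thr_hidden"],
                wt = pool["w_top"];
  NumericVector tt = pool["thr_top"];
  int t1 = as<int>(pool["twist1"]), t2 = as<int>(pool["twist2"]);
  NetBuf net;
  net.feat.resize((size_t)t1 * t2);
  net.wh.resize((size_t)t1 * t2);
  net.th.resize(t2);
  net.wt.resize(t2);
  for (int j = 0; j < t1 * t2; ++j) {
    net.feat[j] = feat(j, p);
    net.wh[j] = wh(j, p);
  }
  for (int k = 0; k < t2; ++k) {
    net.th[k] = th(k, p);
    net.wt[k] = wt(k, p);
  }
  net.tt = tt[p];
  return net;
}

// [[Rcpp::export]]
List cpp_sample_networks(int n_nets, NumericMatrix X, int twist1, int twist2,
                         double seed) {
  const int n = X.nrow(), nf = X.ncol();
  if (twist1 < 1 || twist1 > nf)
    stop("twist1 must be between 1 and the number of features");
  if (twist2 < 1) stop("twist2 must be >= 1");
  if (n < 2) stop("need at least 2 samples to draw thresholds");
  Xoshiro256 rng((uint64_t)seed);
  std::vector<NetBuf> nets(n_nets);
  std::vector<uint8_t> buf(n);
  for (int p = 0; p < n_nets; ++p)
    rbf_sample_and_eval(nets[p], REAL(X), n, nf, twist1, twist2, rng, &buf[0]);
  return rbf_nets_to_list(nets, twist1, twist2);
}

// [[Rcpp::export]]
IntegerMatrix cpp_evaluate_bits(List pool, NumericMatrix X) {
  const int n = X.nrow();
  int t1 = as<int>(pool["twist1"]), t2 = as<int>(pool["twist2"]);
  NumericVector tt = pool["thr_top"];
  const int P = tt.size();
  IntegerMatrix feat = pool["feat"];
  int maxf = -1;
  for (int v = 0; v < feat.size(); ++v) if (feat[v] > maxf) maxf = feat[v];
  if (maxf >= X.ncol()) stop("X has fewer columns than the networks expect");
  IntegerMatrix out(n, P);
  std::vector<uint8_t> buf(n);
  for (int p = 0; p < P; ++p) {
    NetBuf net = net_from_list(pool, p);
    rbf_eval_bits(net, REAL(X), n, t1, t2, &buf[0]);
    for (int i = 0; i < n; ++i) out(i, p) = buf[i];
  }
  return out;
}

// [[Rcpp::export]]
RawVector cpp_evaluate_bits_packed(List pool, NumericMatrix X) {
  const int n = X.nrow();
  int t1 = as<int>(pool["twist1"]), t2 = as<int>(pool["twist2"]);
  NumericVector tt = pool["thr_top"];
  const int P = tt.size();
  IntegerMatrix feat = pool["feat"];
  int maxf = -1;
  for (int v = 0; v < feat.size(); ++v) if (feat[v] > maxf) maxf = feat[v];
  if (maxf >= X.ncol()) stop("X has fewer columns than the networks expect");
  const int wpc = rbf_words_per_col(n);
  RawVector out((R_xlen_t)P * wpc * 8);
  uint64_t *words = (uint64_t *)RAW(out);
  std::vector<uint8_t> buf(n);
  for (int p = 0; p < P; ++p) {
    NetBuf net = net_from_list(pool, p);
    rbf_eval_bits(net, REAL(X), n, t1, t2, &buf[0]);
    rbf_pack_column(&buf[0], n, words + (size_t)p * wpc);
  }
  return out;
}
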