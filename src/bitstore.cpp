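#include <Rcpp.h>
#include "bitpack.h"
using namespace Rcpp;

// [[Rcpp::export]]
RawVector cpp_pack(IntegerMatrix bits) {
  const int n = bits.nrow(), k = bits.ncol();
  const int wpc = rbf_words_per_col(n);
  RawVector out((R_xlen_t)k * wpc * 8);
  uint64_t *words = (uint64_t *)RAW(out);
  std::memset(words, 0, (size_t)k * wpc * 8);
  for (int j = 0; j < k; ++j) {
    uint64_t *col = words + (size_t)j * wpc;
    for (int i = 0; i < n; ++i) {
      int b = bits(i, j);
      if (b != 0 && b != 1)
        stop("bit entries must be 0 or 1 (column %d, row %d)", j + 1, i + 1);
      if (b) col[i >> 6] |= (1ULL << (i & 63));
    }
  }
  return out;
}

// [[Rcpp::export]]
IntegerMatrix cpp_unpack(RawVector words, int n_samples, int n_bits) {
  const int wpc = rbf_words_per_col(n_samples);
  if ((R_xlen_t)n_bits * wpc * 8 != words.size())
    stop("packed buffer size does not match n_samples/n_bits");
  const uint64_t *w = (const uint64_t *)RAW(words);
  IntegerMatrix out(n_samples, n_bits);
  for (int j = 0; j < n_bits; ++j) {
    const uint64_t *col = w + (size_t)j * wpc;
    for (int i = 0; i < n_samples; ++i) out(i, j) = rbf_get_bit(col, i);
  }
  return out;
}

// [[Rcpp::export]]
double cpp_popcount_col(RawVector words, int n_samples, int n_bits, int j) {
  if (j < 0 || j >= n_bits) stop("bit index out of range");
  const int wpc = rbf_words_per_col(n_samples);
  const uint64_t *col = (const uint64_t *)RAW(words) + (size_t)j * wpc;
  double total = 0;
  for (int w = 0; w < wpc; ++w) total += __builtin_popcountll(col[w]);
  return total;
}

// Grouped counts/sums of `values` over `subset` (0-based, repeats allowed),
// split by the stored bit. Returns c(n0, sum0, n1, sum1).
// [[Rcpp::export]]
NumericVector cpp_group_sums(RawVector words, int n_samples, int n_bits,
                             int j, NumericVector values,
                             IntegerVector subset) {
  if (j < 0 || j >= n_bits) stop("bit index out of range");
  if (values.size() != n_samples)
    stop("values must have length n_samples");
  const int wpc = rbf_words_per_col(n_samples);
  const uint64_t *col = (const uint64_t *)RAW(words) + (size_t)j * wpc;
  double n0 = 0, s0 = 0, n1 = 0, s1 = 0;
  for (R_xlen_t t = 0; t < subset.size(); ++t) {
    int i = subset[t];
    if (i < 0 || i >= n_samples) stop("subset index out of range");
    if (rbf_get_bit(col, i)) { n1 += 1; s1 += values[i]; }
    else                     { n0 += 1; s0 += values[i]; }
  }
  return NumericVector::create(n0, s0, n1, s1);
}
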