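#pragma once
#include <cstdint>
#include <cstring>

// Packed binary feature matrix: column-major, 64-bit words, LSB = lowest
// sample index, padding bits past n_samples are zero.

static inline int rbf_words_per_col(int n_samples) {
  return (n_samples + 63) / 64;
}

static inline int rbf_get_bit(const uint64_t *col, int i) {
  return (int)((col[i >> 6] >> (i & 63)) & 1ULL);
}

static inline void rbf_pack_column(const uint8_t *bits, int n, uint64_t *col) {
  int wpc = rbf_words_per_col(n);
  std::memset(col, 0, (size_t)wpc * 8);
  for (int i = 0; i < n; ++i) {
    if (bits[i]) col[i >> 6] |= (1ULL << (i & 63));
  }
}
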