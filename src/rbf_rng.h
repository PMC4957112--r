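#pragma once
#include <cstdint>
#include <cmath>

// Deterministic RNG for the packed-bit core. Substreams (boost chains, trees)
// are derived from a master seed so results are independent of execution order.

static inline uint64_t rbf_splitmix64(uint64_t &state) {
  uint64_t z = (state += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

static inline uint64_t rbf_derive_seed(uint64_t seed, uint64_t stream) {
  uint64_t s = seed ^ (0x9E3779B97F4A7C15ULL * (stream + 1));
  uint64_t a = rbf_splitmix64(s);
  uint64_t b = rbf_splitmix64(s);
  return a ^ (b << 1);
}

struct Xoshiro256 {
  uint64_t s[4];
  explicit Xoshiro256(uint64_t seed) {
    uint64_t sm = seed;
    for (int i = 0; i < 4; ++i) s[i] = rbf_splitmix64(sm);
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = rotl(s[1] * 5, 7) * 9;
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform on [0, 1), 53-bit resolution
  inline double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  // uniform on (0, 1]
  inline double unif_pos() {
    return ((next() >> 11) + 1) * (1.0 / 9007199254740992.0);
  }
  inline int unif_int(int n) {
    int k = (int)(unif() * n);
    return k >= n ? n - 1 : k;
  }
  // Box-Muller; two fresh uniforms per deviate keeps the stream layout simple
  inline double normal() {
    double u1 = unif_pos();
    double u2 = unif();
    return std::sqrt(-2.0 * std::log(u1)) *
           std::cos(6.283185307179586476925287 * u2);
  }
};
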