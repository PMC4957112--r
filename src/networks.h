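#pragma once
#include <vector>
#include <cstdint>
#include "rbf_rng.h"

// One Random Bit network: 3-layer sparse threshold net with random weights.
// Hidden node k reads twist1 distinct features; thresholds are z-values of a
// uniformly drawn training sample; both layers use strict ">" (ties -> 0).
struct NetBuf {
  std::vector<int> feat;     // twist1 * twist2, node-major
  std::vector<double> wh;    // twist1 * twist2
  std::vector<double> th;    // twist2 hidden thresholds
  std::vector<double> wt;    // twist2 top weights
  double tt;                 // top threshold
};

// X is column-major n x nf (an R matrix)
inline double rbf_hidden_z(const NetBuf &net, const double *X, int n,
                           int t1, int k, int i) {
  double z = 0;
  const int base = k * t1;
  for (int j = 0; j < t1; ++j)
    z += net.wh[base + j] * X[i + (size_t)net.feat[base + j] * n];
  return z;
}

// Draw order per network (frozen for reproducibility): for each hidden node,
// twist1 distinct feature indices (rejection sampling), twist1 N(0,1)
// weights, one threshold sample index; then twist2 top weights and one top
// threshold sample index. `out` receives the bit for every training sample.
inline void rbf_sample_and_eval(NetBuf &net, const double *X, int n, int nf,
                                int t1, int t2, Xoshiro256 &rng,
                                uint8_t *out) {
  net.feat.resize((size_t)t1 * t2);
  net.wh.resize((size_t)t1 * t2);
  net.th.resize(t2);
  net.wt.resize(t2);
  for (int k = 0; k < t2; ++k) {
    const int base = k * t1;
    for (int j = 0; j < t1; ++j) {
      int f;
      bool dup;
      do {
        f = rng.unif_int(nf);
        dup = false;
        for (int j2 = 0; j2 < j; ++j2)
          if (net.feat[base + j2] == f) { dup = true; break; }
      } while (dup);
      net.feat[base + j] = f;
    }
    for (int j = 0; j < t1; ++j) net.wh[base + j] = rng.normal();
    int u = rng.unif_int(n);
    net.th[k] = rbf_hidden_z(net, X, n, t1, k, u);
  }
  for (int k = 0; k < t2; ++k) net.wt[k] = rng.normal();
  // top-layer summations over hidden bits for all training samples
  std::vector<double> s((size_t)n, 0.0);
  for (int k = 0; k < t2; ++k) {
    const double w = net.wt[k], thr = net.th[k];
    for (int i = 0; i < n; ++i)
      if (rbf_hidden_z(net, X, n, t1, k, i) > thr) s[i] += w;
  }
  int u = rng.unif_int(n);
  net.tt = s[u];
  for (int i = 0; i < n; ++i) out[i] = (s[i] > net.tt) ? 1 : 0;
}

inline void rbf_eval_bits(const NetBuf &net, const double *X, int n, int t1,
                          int t2, uint8_t *out) {
  std::vector<double> s((size_t)n, 0.0);
  for (int k = 0; k < t2; ++k) {
    const double w = net.wt[k], thr = net.th[k];
    for (int i = 0; i < n; ++i)
      if (rbf_hidden_z(net, X, n, t1, k, i) > thr) s[i] += w;
  }
  for (int i = 0; i < n; ++i) out[i] = (s[i] > net.tt) ? 1 : 0;
}
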