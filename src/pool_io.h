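#pragma once
#include <Rcpp.h>
#include "networks.h"

// Conversions between the flat R pool representation (one column per
// network) and NetBuf. Shared by the sampling, boosting and model code.

inline Rcpp::List rbf_nets_to_list(const std::vector<NetBuf> &nets, int t1,
                                   int t2) {
  using namespace Rcpp;
  const int P = (int)nets.size();
  IntegerMatrix feat(t1 * t2, P);
  NumericMatrix wh(t1 * t2, P), th(t2, P), wt(t2, P);
  NumericVector tt(P);
  for (int p = 0; p < P; ++p) {
    for (int j = 0; j < t1 * t2; ++j) {
      feat(j, p) = nets[p].feat[j];
      wh(j, p) = nets[p].wh[j];
    }
    for (int k = 0; k < t2; ++k) {
      th(k, p) = nets[p].th[k];
      wt(k, p) = nets[p].wt[k];
    }
    tt[p] = nets[p].tt;
  }
  return List::create(_["feat"] = feat, _["w_hidden"] = wh,
                      _["thr_hidden"] = th, _["w_top"] = wt,
                      _["thr_top"] = tt, _["twist1"] = t1, _["twist2"] = t2);
}
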