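#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Core decision loop of the delayed greedy spike rule.
//
// FF:    N x nT feed-forward drive (input filter applied to each neuron's
//        own input), precomputed in R.
// glat:  N*N*L lateral kernel array, glat[m + N*j + N*N*l] = effect on
//        neuron m's membrane potential l steps after a spike of neuron j
//        is decided.
// theta: base thresholds (already include nu).
// df:    per-step decay factor of the adaptive threshold increment.
// mu:    threshold increment per own spike.
// nD:    Delta in bins; decisions run for steps k = nD .. nT-1 (0-based).
// greedy: sequential largest-margin-first within-step resolution (ties to
//        the lowest index); otherwise all suprathreshold neurons fire at
//        once. One spike per neuron per bin in both modes.
//
// [[Rcpp::export]]
List sim_core(NumericMatrix FF, NumericVector glat, int N, int L,
              NumericVector theta, double df, double mu, int nD,
              bool greedy, bool keep_traces) {
  const int nT = FF.ncol();
  std::vector<double> Lbuf((size_t)N * (nT + L), 0.0);
  std::vector<double> adapt(N, 0.0), v(N), thr(N);
  std::vector<char> fired(N);
  std::vector<int> sp_k, sp_m;
  NumericMatrix Vtr(keep_traces ? N : 1, keep_traces ? nT : 1);
  NumericMatrix Ttr(keep_traces ? N : 1, keep_traces ? nT : 1);
  if (keep_traces) {
    std::fill(Vtr.begin(), Vtr.end(), NA_REAL);
    std::fill(Ttr.begin(), Ttr.end(), NA_REAL);
  }
  const double *g = glat.begin();

  for (int k = nD; k < nT; ++k) {
    const size_t col = (size_t)N * k;
    for (int m = 0; m < N; ++m) {
      adapt[m] *= df;
      v[m] = FF(m, k) + Lbuf[col + m];
      thr[m] = theta[m] + adapt[m];
      fired[m] = 0;
    }
    if (keep_traces)
      for (int m = 0; m < N; ++m) Ttr(m, k) = thr[m];

    if (greedy) {
      for (int iter = 0; iter < N; ++iter) {
        int best = -1;
        double bestmar = 0.0;
        for (int m = 0; m < N; ++m) {
          if (fired[m]) continue;
          const double mar = v[m] - thr[m];
          if (mar > bestmar) { bestmar = mar; best = m; }
        }
        if (best < 0) break;
        sp_k.push_back(k); sp_m.push_back(best + 1);
        fired[best] = 1;
        adapt[best] += mu; thr[best] += mu;
        const int nadd = std::min(L, nT + L - k);
        const double *gj = g + (size_t)N * N * 0 + (size_t)N * best;
        for (int l = 0; l < nadd; ++l) {
          double *dst = &Lbuf[(size_t)N * (k + l)];
          const double *src = g + (size_t)N * best + (size_t)N * N * l;
          for (int m = 0; m < N; ++m) dst[m] += src[m];
        }
        (void)gj;
        for (int m = 0; m < N; ++m)
          v[m] = FF(m, k) + Lbuf[col + m];
      }
    } else {
      std::vector<int> who;
      for (int m = 0; m < N; ++m)
        if (v[m] > thr[m]) who.push_back(m);
      for (size_t i = 0; i < who.size(); ++i) {
        const int m0 = who[i];
        sp_k.push_back(k); sp_m.push_back(m0 + 1);
        adapt[m0] += mu;
        const int nadd = std::min(L, nT + L - k);
        for (int l = 0; l < nadd; ++l) {
          double *dst = &Lbuf[(size_t)N * (k + l)];
          const double *src = g + (size_t)N * m0 + (size_t)N * N * l;
          for (int m = 0; m < N; ++m) dst[m] += src[m];
        }
      }
    }
    if (keep_traces)
      for (int m = 0; m < N; ++m) Vtr(m, k) = FF(m, k) + Lbuf[col + m];
  }

  List out = List::create(_["sp_k"] = wrap(sp_k), _["sp_m"] = wrap(sp_m));
  if (keep_traces) { out["membrane"] = Vtr; out["threshold"] = Ttr; }
  return out;
}
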