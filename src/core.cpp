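#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Exact log Z per stimulus row by Gray-code enumeration of all 2^N patterns.
// H is U x N (one row of fields per unique stimulus); J is N x N symmetric,
// zero diagonal, {0,1} coding so the pairwise energy of a pattern sigma is
// sigma' J sigma = 2 * sum_{i<j} J_ij sigma_i sigma_j.
//
// The quadratic term is precomputed once for all patterns (Gray-code update:
// flipping bit i changes it by +/- 2 * sum_{j active} J_ij) and reused across
// stimulus rows; per row only the field dot product changes, by +/- h_i.
// [[Rcpp::export]]
NumericVector exact_logz_cpp(NumericMatrix H, NumericMatrix J) {
  const int U = H.nrow(), N = H.ncol();
  if (N > 30) stop("exact enumeration capped well below N = %d", N);
  const size_t P = ((size_t)1) << N;

  std::vector<double> quad(P);
  std::vector<int> state(N, 0);
  {
    double q = 0.0;
    quad[0] = 0.0;
    for (size_t g = 1; g < P; ++g) {
      // bit flipped between Gray codes of g-1 and g
      size_t gray_prev = (g - 1) ^ ((g - 1) >> 1);
      size_t gray_cur = g ^ (g >> 1);
      size_t diff = gray_prev ^ gray_cur;
      int i = 0;
      while (!((diff >> i) & 1)) ++i;
      double s = 0.0;
      for (int j = 0; j < N; ++j) if (state[j]) s += J(i, j);
      if (state[i]) { state[i] = 0; q -= 2.0 * s; }
      else { q += 2.0 * s; state[i] = 1; }
      quad[gray_cur] = q;
    }
  }

  std::vector<double> logw(P);
  NumericVector out(U);
  for (int u = 0; u < U; ++u) {
    std::fill(state.begin(), state.end(), 0);
    double dot = 0.0, mx = quad[0];
    logw[0] = quad[0];
    for (size_t g = 1; g < P; ++g) {
      size_t gray_prev = (g - 1) ^ ((g - 1) >> 1);
      size_t gray_cur = g ^ (g >> 1);
      size_t diff = gray_prev ^ gray_cur;
      int i = 0;
      while (!((diff >> i) & 1)) ++i;
      if (state[i]) { state[i] = 0; dot -= H(u, i); }
      else { state[i] = 1; dot += H(u, i); }
      double lw = dot + quad[gray_cur];
      logw[gray_cur] = lw;
      if (lw > mx) mx = lw;
    }
    double s = 0.0;
    for (size_t p = 0; p < P; ++p) s += std::exp(logw[p] - mx);
    out[u] = mx + std::log(s);
  }
  return out;
}

// Single-site Gibbs sampler for the stimulus-driven Ising model.
// H is L x N (per-bin fields), J symmetric zero-diagonal. Each bin runs
// burnin + sweeps full sweeps from the previous bin's state (first bin from
// independent draws at logistic(h)); the state after the final sweep is
// recorded. Uses R's RNG so set.seed() governs reproducibility.
// [[Rcpp::export]]
IntegerMatrix gibbs_sample_cpp(NumericMatrix H, NumericMatrix J,
                               int burnin, int sweeps) {
  const int L = H.nrow(), N = H.ncol();
  if (sweeps < 1) stop("sweeps_per_bin must be >= 1");
  IntegerMatrix out(L, N);
  std::vector<int> state(N);
  RNGScope scope;
  for (int i = 0; i < N; ++i) {
    double p = 1.0 / (1.0 + std::exp(-H(0, i)));
    state[i] = (unif_rand() < p) ? 1 : 0;
  }
  const int total = burnin + sweeps;
  for (int t = 0; t < L; ++t) {
    for (int s = 0; s < total; ++s) {
      for (int i = 0; i < N; ++i) {
        double field = H(t, i);
        for (int j = 0; j < N; ++j)
          if (state[j]) field += 2.0 * J(j, i);
        double p = 1.0 / (1.0 + std::exp(-field));
        state[i] = (unif_rand() < p) ? 1 : 0;
      }
    }
    for (int i = 0; i < N; ++i) out(t, i) = state[i];
  }
  return out;
}
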