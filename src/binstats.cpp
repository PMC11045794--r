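#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

#ifdef __GNUC__
static inline int popcount64(uint64_t x) { return __builtin_popcountll(x); }
#else
static inline int popcount64(uint64_t x) {
  int c = 0;
  while (x) { x &= x - 1; ++c; }
  return c;
}
#endif

// Moments of the binarized +-1 representation from sparse up-events.
// up_neuron / up_bin are 0-based indices of (neuron, bin) pairs where the
// neuron fired at least once in that bin. Per-neuron bitsets over bins make
// pair (and requested triplet) co-occurrence counts cheap popcounts.
//
// [[Rcpp::export]]
List cpp_binned_stats(IntegerVector up_neuron, IntegerVector up_bin,
                      int N, int Nb, bool want_pairs,
                      IntegerMatrix triples) {
  const int W = (Nb + 63) / 64;
  std::vector<uint64_t> bits((size_t) N * W, 0ULL);
  std::vector<int> ni(N, 0);
  std::vector<int> kk(Nb, 0);

  const int M = up_neuron.size();
  for (int e = 0; e < M; ++e) {
    const int i = up_neuron[e];
    const int k = up_bin[e];
    uint64_t &w = bits[(size_t) i * W + (k >> 6)];
    const uint64_t m = 1ULL << (k & 63);
    if (!(w & m)) {
      w |= m;
      ++ni[i];
      ++kk[k];
    }
  }

  NumericVector mean_sig(N);
  for (int i = 0; i < N; ++i) mean_sig[i] = 2.0 * ni[i] / Nb - 1.0;

  NumericMatrix pair_sig(want_pairs ? N : 1, want_pairs ? N : 1);
  if (want_pairs) {
    for (int i = 0; i < N; ++i) {
      pair_sig(i, i) = 1.0;
      const uint64_t *bi = &bits[(size_t) i * W];
      for (int j = i + 1; j < N; ++j) {
        const uint64_t *bj = &bits[(size_t) j * W];
        long long nij = 0;
        for (int w = 0; w < W; ++w) nij += popcount64(bi[w] & bj[w]);
        const double v = ((double) Nb - 2.0 * (ni[i] + ni[j]) + 4.0 * nij) / Nb;
        pair_sig(i, j) = v;
        pair_sig(j, i) = v;
      }
    }
  }

  NumericVector pk(N + 1);
  for (int k = 0; k < Nb; ++k) pk[kk[k]] += 1.0;
  pk = pk / (double) Nb;

  const int ntr = triples.nrow();
  NumericVector trip(ntr);
  if (ntr > 0) {
    for (int t = 0; t < ntr; ++t) {
      const int i = triples(t, 0), j = triples(t, 1), k = triples(t, 2);
      const uint64_t *bi = &bits[(size_t) i * W];
      const uint64_t *bj = &bits[(size_t) j * W];
      const uint64_t *bk = &bits[(size_t) k * W];
      long long nij = 0, nik = 0, njk = 0, nijk = 0;
      for (int w = 0; w < W; ++w) {
        const uint64_t ab = bi[w] & bj[w];
        nij += popcount64(ab);
        nik += popcount64(bi[w] & bk[w]);
        njk += popcount64(bj[w] & bk[w]);
        nijk += popcount64(ab & bk[w]);
      }
      // <sigma_i sigma_j sigma_k> from up-counts (sigma = 2x - 1)
      trip[t] = (8.0 * nijk - 4.0 * (nij + nik + njk)
                 + 2.0 * (ni[i] + ni[j] + ni[k])) / Nb - 1.0;
    }
  }

  return List::create(
    _["mean_sigma"] = mean_sig,
    _["pair_sigma"] = pair_sig,
    _["pk"] = pk,
    _["triple_raw"] = trip,
    _["n_bins"] = Nb);
}
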