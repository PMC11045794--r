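#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Single-spin-flip Metropolis sampler for the pairwise Ising model
//   H(sigma) = -sum_i h_i sigma_i - sum_{i<j} J_ij sigma_i sigma_j
// at temperature T. One "configuration" is one attempted flip of a
// uniformly chosen spin; the first burn_in attempts are discarded, then
// every thin-th configuration is retained until n_retain samples are
// collected. Local fields b_i = h_i + sum_j J_ij sigma_j are cached so an
// attempt costs O(1) and an accepted flip O(N).
//
// [[Rcpp::export]]
List cpp_metropolis(NumericVector h, NumericMatrix J, double T,
                    int n_retain, int burn_in, int thin, int init,
                    bool collect_pairs, bool collect_series,
                    bool collect_pk, IntegerVector sigma0) {
  const int N = h.size();
  std::vector<int> sigma(N);
  if (sigma0.size() == N) {
    for (int i = 0; i < N; ++i) sigma[i] = (sigma0[i] > 0) ? 1 : -1;
  } else if (init == 1) {
    for (int i = 0; i < N; ++i) sigma[i] = -1;
  } else {
    for (int i = 0; i < N; ++i) sigma[i] = (unif_rand() < 0.5) ? -1 : 1;
  }

  std::vector<double> b(N);
  double H = 0.0;
  int M = 0;
  for (int i = 0; i < N; ++i) {
    double s = h[i];
    for (int j = 0; j < N; ++j) s += J(i, j) * sigma[j];
    b[i] = s;
    H -= h[i] * sigma[i];
    M += sigma[i];
  }
  for (int i = 0; i < N; ++i)
    for (int j = i + 1; j < N; ++j) H -= J(i, j) * sigma[i] * sigma[j];

  NumericVector sum_sig(N);
  NumericMatrix sum_pair(collect_pairs ? N : 1, collect_pairs ? N : 1);
  NumericVector M_series(collect_series ? n_retain : 0);
  NumericVector E_series(collect_series ? n_retain : 0);
  NumericVector pk(collect_pk ? N + 1 : 0);

  long long attempts = 0;
  long long accepted = 0;
  int retained = 0;
  int since_retain = 0;

  while (retained < n_retain) {
    int i = (int) std::floor(unif_rand() * N);
    if (i >= N) i = N - 1;
    const double dH = 2.0 * sigma[i] * b[i];
    ++attempts;
    if (dH <= 0.0 || unif_rand() < std::exp(-dH / T)) {
      const int old = sigma[i];
      sigma[i] = -old;
      H += dH;
      M -= 2 * old;
      const double delta = -2.0 * old;
      for (int j = 0; j < N; ++j) b[j] += delta * J(j, i);
      ++accepted;
    }
    if (attempts <= burn_in) continue;
    if (++since_retain < thin) continue;
    since_retain = 0;
    for (int k = 0; k < N; ++k) sum_sig[k] += sigma[k];
    if (collect_pairs)
      for (int a = 0; a < N; ++a) {
        if (sigma[a] < 0) continue;
        for (int c = a + 1; c < N; ++c) sum_pair(a, c) += sigma[c];
      }
    if (collect_series) {
      M_series[retained] = M;
      E_series[retained] = -H;
    }
    if (collect_pk) pk[(M + N) / 2] += 1.0;
    ++retained;
  }

  NumericVector mean_sig = sum_sig / (double) n_retain;
  NumericMatrix pair_sig(1, 1);
  if (collect_pairs) {
    // sum_pair holds sum over samples of sigma_c restricted to sigma_a = +1;
    // recover <sigma_a sigma_c> = 2*sum(sigma_c | a up)/n - <sigma_c>.
    pair_sig = NumericMatrix(N, N);
    for (int a = 0; a < N; ++a) {
      pair_sig(a, a) = 1.0;
      for (int c = a + 1; c < N; ++c) {
        const double v = 2.0 * sum_pair(a, c) / (double) n_retain - mean_sig[c];
        pair_sig(a, c) = v;
        pair_sig(c, a) = v;
      }
    }
  }
  if (collect_pk) pk = pk / (double) n_retain;

  return List::create(
    _["mean_sigma"] = mean_sig,
    _["pair_sigma"] = pair_sig,
    _["M"] = M_series,
    _["E"] = E_series,
    _["pk"] = pk,
    _["n_retain"] = retained,
    _["accept_rate"] = (double) accepted / (double) attempts,
    _["sigma_final"] = IntegerVector(sigma.begin(), sigma.end()));
}

// Exact thermal averages by full enumeration of the 2^N states (Gray-code
// walk; one spin flips between consecutive states). N <= 20 guard is at the
// R level. Returns moments plus <M>, <M^2>, <E>, <E^2>, P(K) and log Z.
//
// [[Rcpp::export]]
List cpp_exact_moments(NumericVector h, NumericMatrix J, double T) {
  const int N = h.size();
  const long long S = 1LL << N;

  std::vector<int> sigma(N, -1);
  std::vector<double> b(N);
  double H = 0.0;
  for (int i = 0; i < N; ++i) {
    double s = h[i];
    for (int j = 0; j < N; ++j) s += J(i, j) * sigma[j];
    b[i] = s;
    H -= h[i] * sigma[i];
  }
  for (int i = 0; i < N; ++i)
    for (int j = i + 1; j < N; ++j) H -= J(i, j) * sigma[i] * sigma[j];
  const double H0 = H;

  // pass 1: minimum H over states
  double Hmin = H;
  {
    double Hc = H;
    long long gray_prev = 0;
    for (long long s = 1; s < S; ++s) {
      long long gray = s ^ (s >> 1);
      long long diff = gray ^ gray_prev;
      int i = 0;
      while (!((diff >> i) & 1)) ++i;
      const double dH = 2.0 * sigma[i] * b[i];
      const int old = sigma[i];
      sigma[i] = -old;
      Hc += dH;
      const double delta = -2.0 * old;
      for (int j = 0; j < N; ++j) b[j] += delta * J(j, i);
      if (Hc < Hmin) Hmin = Hc;
      gray_prev = gray;
    }
    // reset state to all-down
    for (int i = 0; i < N; ++i) sigma[i] = -1;
    for (int i = 0; i < N; ++i) {
      double sum = h[i];
      for (int j = 0; j < N; ++j) sum += J(i, j) * sigma[j];
      b[i] = sum;
    }
    H = H0;
  }

  // pass 2: weighted accumulation
  NumericVector mean_sig(N);
  NumericMatrix pair_sig(N, N);
  NumericVector pk(N + 1);
  double Z = 0.0, sM = 0.0, sM2 = 0.0, sE = 0.0, sE2 = 0.0;
  int M = -N;
  long long gray_prev = 0;
  for (long long s = 0; s < S; ++s) {
    if (s > 0) {
      long long gray = s ^ (s >> 1);
      long long diff = gray ^ gray_prev;
      int i = 0;
      while (!((diff >> i) & 1)) ++i;
      const double dH = 2.0 * sigma[i] * b[i];
      const int old = sigma[i];
      sigma[i] = -old;
      H += dH;
      M -= 2 * old;
      const double delta = -2.0 * old;
      for (int j = 0; j < N; ++j) b[j] += delta * J(j, i);
      gray_prev = gray;
    }
    const double w = std::exp(-(H - Hmin) / T);
    Z += w;
    const double E = -H;
    sM += w * M; sM2 += w * (double) M * M;
    sE += w * E; sE2 += w * E * E;
    pk[(M + N) / 2] += w;
    for (int i = 0; i < N; ++i) {
      mean_sig[i] += w * sigma[i];
      if (sigma[i] < 0) continue;
      for (int j = i + 1; j < N; ++j) pair_sig(i, j) += w * sigma[j];
    }
  }

  for (int i = 0; i < N; ++i) mean_sig[i] /= Z;
  for (int i = 0; i < N; ++i) {
    for (int j = i + 1; j < N; ++j) {
      const double v = 2.0 * pair_sig(i, j) / Z - mean_sig[j];
      pair_sig(i, j) = v;
      pair_sig(j, i) = v;
    }
    pair_sig(i, i) = 1.0;
  }
  pk = pk / Z;

  return List::create(
    _["mean_sigma"] = mean_sig,
    _["pair_sigma"] = pair_sig,
    _["pk"] = pk,
    _["mean_M"] = sM / Z,
    _["mean_M2"] = sM2 / Z,
    _["mean_E"] = sE / Z,
    _["mean_E2"] = sE2 / Z,
    _["logZ"] = std::log(Z) - Hmin / T);
}

// Metropolis sampling that returns the retained configurations themselves,
// as sparse up-state events (spin index, sample index), for use as a
// synthetic raster with known ground truth.
//
// [[Rcpp::export]]
List cpp_metropolis_raster(NumericVector h, NumericMatrix J, double T,
                           int n_keep, int burn_in, int thin, int init) {
  const int N = h.size();
  std::vector<int> sigma(N);
  if (init == 1) for (int i = 0; i < N; ++i) sigma[i] = -1;
  else for (int i = 0; i < N; ++i) sigma[i] = (unif_rand() < 0.5) ? -1 : 1;

  std::vector<double> b(N);
  for (int i = 0; i < N; ++i) {
    double s = h[i];
    for (int j = 0; j < N; ++j) s += J(i, j) * sigma[j];
    b[i] = s;
  }

  std::vector<int> up_i, up_k;
  long long attempts = 0;
  int kept = 0, since = 0;
  while (kept < n_keep) {
    int i = (int) std::floor(unif_rand() * N);
    if (i >= N) i = N - 1;
    const double dH = 2.0 * sigma[i] * b[i];
    ++attempts;
    if (dH <= 0.0 || unif_rand() < std::exp(-dH / T)) {
      const int old = sigma[i];
      sigma[i] = -old;
      const double delta = -2.0 * old;
      for (int j = 0; j < N; ++j) b[j] += delta * J(j, i);
    }
    if (attempts <= burn_in) continue;
    if (++since < thin) continue;
    since = 0;
    for (int s = 0; s < N; ++s)
      if (sigma[s] > 0) { up_i.push_back(s); up_k.push_back(kept); }
    ++kept;
  }
  return List::create(_["up_i"] = IntegerVector(up_i.begin(), up_i.end()),
                      _["up_k"] = IntegerVector(up_k.begin(), up_k.end()),
                      _["n_keep"] = kept);
}
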