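#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Integrate-and-fire engine on a directed weighted graph.
//
// Synchronous update per timestep t:
//   1. firers = non-refractory neurons with v > v_c (state at start of step);
//   2. all propagations applied simultaneously to non-refractory targets,
//      v_j += sign_i * v_i * u_i * g_ij (/ sum_k g_ik when normalize_out),
//      clipped below at v_min;
//   3. firers: u *= (1 - delta_u), v = 0, refractory through t + t_r;
//   4. external drive +delta_v to one uniform neuron, dropped if that neuron
//      is refractory at t + 1 (a just-fired neuron receives nothing).
// A silent timestep closes an avalanche: all u recharged by delta_u_rec
// (clipped at 1); in shaping mode the homeostatic LTP decrease is applied.
//
// Uses R's RNG stream (deterministic under set.seed()).
//
// [[Rcpp::export]]
List cpp_simulate_if(IntegerVector out_ptr, IntegerVector out_idx,
                     NumericVector g_edge, IntegerVector sign,
                     List params, int max_steps, int n_aval_target,
                     bool ltp, bool record, int burn_in, int watchdog,
                     bool normalize_out,
                     NumericVector v0, NumericVector u0) {
  const int N = out_ptr.size() - 1;
  const double v_c   = as<double>(params["v_c"]);
  const double v_min = as<double>(params["v_min"]);
  const double du    = as<double>(params["delta_u"]);
  const double du_rec = as<double>(params["delta_u_rec"]);
  const double dv    = as<double>(params["delta_v"]);
  const int    t_r   = as<int>(params["t_r"]);
  const double beta  = as<double>(params["beta"]);
  const double g_min = as<double>(params["g_min"]);
  const int n_edges = g_edge.size();

  std::vector<double> v(N), u(N, 1.0);
  std::vector<int> refract_until(N, -1);
  if (v0.size() == N) {
    for (int i = 0; i < N; ++i) v[i] = v0[i];
  } else {
    for (int i = 0; i < N; ++i) v[i] = unif_rand() * v_c;
  }
  if (u0.size() == N)
    for (int i = 0; i < N; ++i) u[i] = u0[i];

  std::vector<double> g(g_edge.begin(), g_edge.end());
  // per-source outgoing strength sums for the normalized efficacy
  std::vector<double> sumg(N, 0.0);
  for (int i = 0; i < N; ++i)
    for (int e = out_ptr[i]; e < out_ptr[i + 1]; ++e) sumg[i] += g[e];
  std::vector<int> counts;
  counts.reserve(max_steps > 0 ? std::min(max_steps, 1 << 20) : 1024);
  std::vector<int> ev_t, ev_n;
  std::vector<int> firers;
  firers.reserve(N);

  bool in_aval = false;
  int aval_count = 0;
  double sum_dg = 0.0;
  int last_activity = 0;
  int stop_reason = 0; // 0 = max_steps, 1 = n_aval reached, 2 = g_min hit
  bool watchdog_hit = false;
  int t = 0;

  for (t = 0; t < max_steps; ++t) {
    firers.clear();
    for (int i = 0; i < N; ++i)
      if (refract_until[i] < t && v[i] > v_c) firers.push_back(i);
    const int nf = (int) firers.size();
    counts.push_back(nf);

    if (nf > 0) {
      last_activity = t;
      if (record && t >= burn_in)
        for (int k = 0; k < nf; ++k) { ev_t.push_back(t); ev_n.push_back(firers[k]); }
      for (int k = 0; k < nf; ++k) {
        const int i = firers[k];
        const double vi = v[i], ui = u[i];
        const double s = (sign[i] > 0) ? 1.0 : -1.0;
        const double norm = (normalize_out && sumg[i] > 0.0)
                              ? 1.0 / sumg[i] : 1.0;
        for (int e = out_ptr[i]; e < out_ptr[i + 1]; ++e) {
          const int j = out_idx[e];
          if (refract_until[j] >= t) continue; // refractory: receives nothing
          const double dvij = vi * ui * g[e] * norm;
          v[j] += s * dvij;
          if (v[j] < v_min) v[j] = v_min;
          if (ltp) {
            const double dg = beta * dvij;
            g[e] += dg;
            if (g[e] > 1.0) g[e] = 1.0;
            sumg[i] += dg;
            sum_dg += dg;
          }
        }
      }
      for (int k = 0; k < nf; ++k) {
        const int i = firers[k];
        u[i] *= (1.0 - du);
        v[i] = 0.0;
        refract_until[i] = t + t_r;
      }
      in_aval = true;
    } else {
      if (in_aval) {
        ++aval_count;
        for (int i = 0; i < N; ++i) {
          u[i] += du_rec;
          if (u[i] > 1.0) u[i] = 1.0;
        }
        if (ltp) {
          const double dec = sum_dg / (double) n_edges;
          sum_dg = 0.0;
          bool hit = false;
          for (int e = 0; e < n_edges; ++e) {
            g[e] -= dec;
            if (g[e] <= g_min) { g[e] = g_min; hit = true; }
          }
          for (int i = 0; i < N; ++i) {
            sumg[i] = 0.0;
            for (int e = out_ptr[i]; e < out_ptr[i + 1]; ++e)
              sumg[i] += g[e];
          }
          if (hit) { stop_reason = 2; ++t; break; }
        }
        if (n_aval_target > 0 && aval_count >= n_aval_target) {
          stop_reason = 1; ++t; break;
        }
      }
      in_aval = false;
      if (watchdog > 0 && t - last_activity > watchdog) watchdog_hit = true;
    }

    // external drive: dropped if the chosen neuron is refractory next step
    int target = (int) std::floor(unif_rand() * N);
    if (target >= N) target = N - 1;
    if (refract_until[target] < t + 1) {
      v[target] += dv;
      if (!std::isfinite(v[target]))
        stop("internal consistency error: non-finite membrane potential");
    }
  }

  return List::create(
    _["counts"] = IntegerVector(counts.begin(), counts.end()),
    _["event_t"] = IntegerVector(ev_t.begin(), ev_t.end()),
    _["event_n"] = IntegerVector(ev_n.begin(), ev_n.end()),
    _["n_steps"] = t,
    _["n_avalanches"] = aval_count,
    _["g"] = NumericVector(g.begin(), g.end()),
    _["u"] = NumericVector(u.begin(), u.end()),
    _["v"] = NumericVector(v.begin(), v.end()),
    _["stop_reason"] = stop_reason,
    _["watchdog_hit"] = watchdog_hit);
}
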