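#include <Rcpp.h>
using namespace Rcpp;

// Continuous-time Markov chain dwell segments for a set of burst envelopes.
// Q: generator matrix (off-diagonal rates, s^-1), p0: initial distribution.
// Returns parallel vectors (burst, state, t0, t1) with times relative to the
// burst start; dwells tile each burst exactly. Uses R's RNG so results are
// reproducible under set.seed().
// [[Rcpp::export]]
List sim_ctmc_segments(NumericVector durations, NumericMatrix Q,
                       NumericVector p0) {
  int ns = Q.nrow();
  std::vector<double> exit(ns);
  std::vector<std::vector<double>> cumjump(ns, std::vector<double>(ns, 0.0));
  for (int i = 0; i < ns; ++i) {
    double tot = 0.0;
    for (int j = 0; j < ns; ++j) if (j != i) tot += Q(i, j);
    exit[i] = tot;
    double c = 0.0;
    for (int j = 0; j < ns; ++j) {
      if (j != i && tot > 0) c += Q(i, j) / tot;
      cumjump[i][j] = c;
    }
  }
  std::vector<double> cump0(ns);
  double c0 = 0.0;
  for (int i = 0; i < ns; ++i) { c0 += p0[i]; cump0[i] = c0; }

  std::vector<int> burst, state;
  std::vector<double> t0v, t1v;
  size_t guess = durations.size() * 4;
  burst.reserve(guess); state.reserve(guess);
  t0v.reserve(guess); t1v.reserve(guess);

  for (int b = 0; b < durations.size(); ++b) {
    double T = durations[b], t = 0.0;
    double u = unif_rand();
    int s = 0;
    while (s < ns - 1 && u > cump0[s] / c0) ++s;
    while (t < T) {
      double dwell = (exit[s] > 0) ? exp_rand() / exit[s] : (T - t);
      double tend = std::min(t + dwell, T);
      burst.push_back(b + 1); state.push_back(s + 1);
      t0v.push_back(t); t1v.push_back(tend);
      t = tend;
      if (t >= T) break;
      double v = unif_rand();
      int nxt = 0;
      while (nxt < ns - 1 && v > cumjump[s][nxt]) ++nxt;
      s = nxt;
    }
  }
  return List::create(_["burst"] = wrap(burst), _["state"] = wrap(state),
                      _["t0"] = wrap(t0v), _["t1"] = wrap(t1v));
}

// Burst-restricted weighted photon-pair correlator.
// times: photon times (s), sorted within bursts; burst: integer id per
// photon (photons of one burst contiguous); w1, w2: per-photon species
// weights; lag_edges: increasing lag-bin edges (s).
// Accumulates ordered pairs (i before j) within the same burst into lag bins
// for the products w1*w1, w2*w2, w1*w2 and w2*w1, plus the independence
// normalisation computed from per-burst weight sums, duration and the
// overlap factor (T - tau) of each lag bin.
// [[Rcpp::export]]
List pair_correlate(NumericVector times, IntegerVector burst,
                    NumericVector w1, NumericVector w2,
                    NumericVector lag_edges,
                    NumericVector burst_t0, NumericVector burst_t1) {
  int nb = lag_edges.size() - 1;
  NumericVector g11(nb), g22(nb), g12(nb), g21(nb), gtt(nb);
  NumericVector n11(nb), n22(nb), n12(nb), ngeo(nb);
  double wsum1 = 0.0, wsum2 = 0.0, tsum = 0.0;
  double nphot = 0.0;
  double max_lag = lag_edges[nb];
  int n = times.size();
  int i = 0;
  while (i < n) {
    int b = burst[i];
    int jend = i;
    while (jend < n && burst[jend] == b) ++jend;
    // pair accumulation
    for (int a = i; a < jend; ++a) {
      for (int c = a + 1; c < jend; ++c) {
        double dt = times[c] - times[a];
        if (dt >= max_lag) break;
        if (dt < lag_edges[0]) continue;
        // binary search for bin
        int lo = 0, hi = nb;
        while (hi - lo > 1) {
          int mid = (lo + hi) / 2;
          if (dt >= lag_edges[mid]) lo = mid; else hi = mid;
        }
        g11[lo] += w1[a] * w1[c];
        g22[lo] += w2[a] * w2[c];
        g12[lo] += w1[a] * w2[c];
        g21[lo] += w2[a] * w1[c];
        gtt[lo] += 1.0;
      }
    }
    // normalisation for this burst: E[pairs] under independence with
    // uniform intensity over [t0, t1]
    double W1 = 0.0, W2 = 0.0;
    for (int a = i; a < jend; ++a) { W1 += w1[a]; W2 += w2[a]; }
    double T = burst_t1[b - 1] - burst_t0[b - 1];
    if (T > 0) {
      wsum1 += W1; wsum2 += W2; tsum += T;
      nphot += jend - i;
      for (int k = 0; k < nb; ++k) {
        double lo = lag_edges[k], hi = std::min(lag_edges[k + 1], T);
        if (hi <= lo) continue;
        // integral over ordered pairs: (T - tau) dtau / T^2
        double ov = ((T - lo) * (T - lo) - (T - hi) * (T - hi)) / (2.0 * T * T);
        n11[k] += W1 * W1 * ov;
        n22[k] += W2 * W2 * ov;
        n12[k] += W1 * W2 * ov;
        ngeo[k] += T * T * ov;
      }
    }
    i = jend;
  }
  return List::create(_["g11"] = g11, _["g22"] = g22, _["g12"] = g12,
                      _["g21"] = g21, _["gtt"] = gtt, _["n11"] = n11,
                      _["n22"] = n22, _["n12"] = n12, _["ngeo"] = ngeo,
                      _["wsum1"] = wsum1, _["wsum2"] = wsum2,
                      _["tsum"] = tsum, _["nphot"] = nphot);
}
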