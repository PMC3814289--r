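// Gillespie Direct Method kernel for networks whose rate laws are all
// mass action (density form: T_mu(n) = Omega * k_mu * prod_i (n_i/Omega)^r_imu).
// Accumulates time-weighted stationary moments in equal-width batch-mean
// blocks over (burn_in, t_end]; optionally records the event trajectory.
// Uses R's RNG so set.seed() in R gives reproducible runs.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
List ssa_mass_action_cpp(IntegerMatrix nu, IntegerMatrix rstoich,
                         NumericVector rate_const, double omega,
                         NumericVector n0, double t_end, double burn_in,
                         int n_blocks, bool record, int max_record,
                         double max_events) {
  const int K = nu.nrow(), M = nu.ncol();
  std::vector<double> n(n0.begin(), n0.end());
  std::vector<double> props(M);

  // flat sparse structure per reaction: reactant orders and state changes
  std::vector<std::vector<std::pair<int, int>>> react(M), change(M);
  for (int m = 0; m < M; ++m) {
    for (int i = 0; i < K; ++i) {
      if (rstoich(i, m) > 0) react[m].push_back({i, rstoich(i, m)});
      if (nu(i, m) != 0) change[m].push_back({i, nu(i, m)});
    }
  }

  std::vector<double> rec_t;
  std::vector<double> rec_s;
  if (record) {
    rec_t.reserve(1024);
    rec_s.reserve(1024 * K);
    rec_t.push_back(0.0);
    for (int i = 0; i < K; ++i) rec_s.push_back(n[i]);
  }

  // block accumulators over (burn_in, t_end]
  const double bw = (t_end - burn_in) / n_blocks;
  std::vector<double> bT(n_blocks, 0.0), bS1((size_t)n_blocks * K, 0.0),
      bS2((size_t)n_blocks * K * K, 0.0);
  int cur_blk = 0;
  double cur_edge = burn_in + bw;

  auto add_seg = [&](int blk, double seg) {
    bT[blk] += seg;
    double *s1 = &bS1[(size_t)blk * K];
    double *s2 = &bS2[(size_t)blk * K * K];
    for (int i = 0; i < K; ++i) {
      const double wni = seg * n[i];
      s1[i] += wni;
      for (int j = 0; j <= i; ++j) s2[(size_t)i * K + j] += wni * n[j];
    }
  };
  auto accumulate = [&](double t0, double t1) {
    // state n held over [t0, t1); clip to (burn_in, t_end]; intervals
    // arrive in increasing time order, so the current block only advances
    if (t1 <= burn_in || t0 >= t_end) return;
    double a = t0 < burn_in ? burn_in : t0;
    double b = t1 > t_end ? t_end : t1;
    if (b <= cur_edge) {           // hot path: stays in the current block
      if (b > a) add_seg(cur_blk, b - a);
      return;
    }
    while (true) {
      bool last = cur_blk == n_blocks - 1;
      double stop = (last || b < cur_edge) ? b : cur_edge;
      if (stop > a) add_seg(cur_blk, stop - a);
      a = stop;
      if (a >= b) break;
      ++cur_blk;
      cur_edge = burn_in + (cur_blk + 1) * bw;
    }
  };

  RNGScope scope;
  double t = 0.0, events = 0.0;
  bool absorbed = false, truncated = false;

  while (t < t_end) {
    double a0 = 0.0;
    for (int m = 0; m < M; ++m) {
      double p = rate_const[m] * omega;
      for (auto &pr : react[m])
        for (int q = 0; q < pr.second; ++q) p *= n[pr.first] / omega;
      props[m] = p;
      a0 += p;
    }
    if (a0 <= 0.0) { absorbed = true; break; }
    double dt = exp_rand() / a0;
    double tn = t + dt;
    accumulate(t, tn);
    if (tn >= t_end) { t = t_end; break; }
    double u = unif_rand() * a0, c = 0.0;
    int mu = M - 1;
    for (int m = 0; m < M; ++m) {
      c += props[m];
      if (u <= c) { mu = m; break; }
    }
    for (auto &pr : change[mu]) n[pr.first] += pr.second;
    t = tn;
    events += 1.0;
    if (record && (int)rec_t.size() < max_record) {
      rec_t.push_back(t);
      for (int i = 0; i < K; ++i) rec_s.push_back(n[i]);
    }
    if (events >= max_events) { truncated = true; break; }
    if (((long long)events & 0xFFFFF) == 0) checkUserInterrupt();
  }
  // absorbed or truncated: the final state holds to t_end
  if (t < t_end) accumulate(t, t_end);

  NumericMatrix states;
  NumericVector times;
  if (record) {
    int nr = rec_t.size();
    times = NumericVector(rec_t.begin(), rec_t.end());
    states = NumericMatrix(nr, K);
    for (int r = 0; r < nr; ++r)
      for (int i = 0; i < K; ++i) states(r, i) = rec_s[(size_t)r * K + i];
  }

  NumericVector blockT(bT.begin(), bT.end());
  NumericMatrix blockS1(n_blocks, K), blockS2(n_blocks, K * K);
  for (int b = 0; b < n_blocks; ++b) {
    for (int i = 0; i < K; ++i) blockS1(b, i) = bS1[(size_t)b * K + i];
    for (int i = 0; i < K; ++i)
      for (int j = 0; j < K; ++j) {
        double v = (j <= i) ? bS2[(size_t)b * K * K + (size_t)i * K + j]
                            : bS2[(size_t)b * K * K + (size_t)j * K + i];
        blockS2(b, i * K + j) = v;
      }
  }
  NumericVector nfinal(n.begin(), n.end());
  return List::create(_["times"] = times, _["states"] = states,
                      _["final_state"] = nfinal, _["n_events"] = events,
                      _["absorbed"] = absorbed, _["truncated"] = truncated,
                      _["t_final"] = t < t_end ? t : t_end,
                      _["block_time"] = blockT, _["block_s1"] = blockS1,
                      _["block_s2"] = blockS2);
}
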