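#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Discrete-time point-neuron update loop.
//
// Per step s = 1..steps:
//   1. synaptic input arriving at s (ring buffer) plus scheduled injections
//   2. v <- resting + decay * (v - resting) + input
//   3. neuron fires iff refractory counter is 0 and v - adapt - fatigue >= threshold
//   4. fired:   v <- reset, refractory <- refrac, adapt += adapt_inc,
//               fatigue += fat_inc; spikes propagate to arrive at s + delay
//      silent:  refractory counter decrements, fatigue recovers by fat_rec
//   5. adapt <- adapt * adapt_dec (retention fraction) for all neurons
//
// `decay` and `adapt_dec` are retention fractions per step in (0, 1].
// Synapses are in CSR layout keyed by presynaptic neuron (0-based).
// `pending` carries deliveries scheduled beyond a previous call's horizon:
// columns (relative step >= 1, neuron 0-based, weight).
//
// Neurons whose state has relaxed to rest and that receive no input are
// kept on an inactive list and skipped; a neuron is snapped to its resting
// state when the residual potential falls below 1e-9 (far below any
// threshold), so the dynamics are unchanged to that tolerance.

// [[Rcpp::export]]
List run_core(int steps,
              NumericVector decay, NumericVector thr, NumericVector resting,
              NumericVector vreset, IntegerVector refrac,
              NumericVector adapt_inc, NumericVector adapt_dec,
              NumericVector fat_inc, NumericVector fat_rec,
              IntegerVector syn_ptr, IntegerVector syn_post,
              NumericVector syn_w, IntegerVector syn_d,
              NumericVector v0, NumericVector a0, NumericVector f0,
              IntegerVector r0,
              NumericMatrix pending,
              IntegerVector in_step, IntegerVector in_idx, NumericVector in_val,
              int t0, int max_delay) {
  const int n = decay.size();
  const int D = max_delay + 1;
  const double tiny = 1e-9;
  std::vector<double> ring((size_t)D * n, 0.0);
  std::vector<double> v(v0.begin(), v0.end());
  std::vector<double> a(a0.begin(), a0.end());
  std::vector<double> f(f0.begin(), f0.end());
  std::vector<int>    r(r0.begin(), r0.end());

  // touched[slot * n + i] marks ring entries worth reading
  std::vector<std::vector<int>> ring_hits(D);
  std::vector<char> ring_mark((size_t)D * n, 0);
  auto ring_add = [&](int slot, int ni, double w) {
    size_t k = (size_t)slot * n + ni;
    ring[k] += w;
    if (!ring_mark[k]) { ring_mark[k] = 1; ring_hits[slot].push_back(ni); }
  };

  for (int k = 0; k < pending.nrow(); ++k) {
    int rs = (int)pending(k, 0);
    int ni = (int)pending(k, 1);
    if (rs >= 1 && rs <= max_delay && ni >= 0 && ni < n)
      ring_add(rs % D, ni, pending(k, 2));
  }

  // active set: any neuron away from its resting state
  std::vector<char> on(n, 0);
  std::vector<int> active;
  active.reserve(256);
  for (int i = 0; i < n; ++i)
    if (std::fabs(v[i] - resting[i]) > tiny || a[i] > tiny || f[i] > tiny ||
        r[i] > 0) { on[i] = 1; active.push_back(i); }

  std::vector<int> sp_step, sp_idx;
  sp_step.reserve(1024); sp_idx.reserve(1024);

  int ip = 0;
  const int nin = in_step.size();
  const double eps = 1e-9;
  std::vector<int> cur;
  cur.reserve(512);

  for (int s = 1; s <= steps; ++s) {
    const int slot = s % D;
    double *inrow = &ring[(size_t)slot * n];

    // candidates: previously active neurons plus anything receiving input
    cur.clear();
    cur.swap(active);
    for (int ni : ring_hits[slot]) if (!on[ni]) { on[ni] = 1; cur.push_back(ni); }
    while (ip < nin && in_step[ip] == s) {
      int ni = in_idx[ip];
      inrow[ni] += in_val[ip];
      if (!ring_mark[(size_t)slot * n + ni]) {
        ring_mark[(size_t)slot * n + ni] = 1; ring_hits[slot].push_back(ni);
      }
      if (!on[ni]) { on[ni] = 1; cur.push_back(ni); }
      ++ip;
    }

    for (int ni : cur) {
      v[ni] = resting[ni] + decay[ni] * (v[ni] - resting[ni]) + inrow[ni];
      bool fire = (r[ni] == 0) && (v[ni] - a[ni] - f[ni] >= thr[ni] - eps);
      if (fire) {
        sp_step.push_back(t0 + s);
        sp_idx.push_back(ni);
        v[ni] = vreset[ni];
        r[ni] = refrac[ni];
        a[ni] += adapt_inc[ni];
        f[ni] += fat_inc[ni];
        for (int k = syn_ptr[ni]; k < syn_ptr[ni + 1]; ++k)
          ring_add((s + syn_d[k]) % D, syn_post[k], syn_w[k]);
      } else {
        if (r[ni] > 0) --r[ni];
        f[ni] -= fat_rec[ni];
        if (f[ni] < 0.0) f[ni] = 0.0;
      }
      a[ni] *= adapt_dec[ni];
      if (a[ni] < tiny) a[ni] = 0.0;
      // keep or retire
      if (std::fabs(v[ni] - resting[ni]) > tiny || a[ni] > 0.0 ||
          f[ni] > tiny || r[ni] > 0) {
        active.push_back(ni);
      } else {
        v[ni] = resting[ni]; f[ni] = 0.0; on[ni] = 0;
      }
    }
    // clear this slot of the ring for reuse
    for (int ni : ring_hits[slot]) {
      ring[(size_t)slot * n + ni] = 0.0;
      ring_mark[(size_t)slot * n + ni] = 0;
    }
    ring_hits[slot].clear();
  }

  // export deliveries still in flight
  std::vector<double> pd, pi, pw;
  for (int d = 1; d <= max_delay; ++d) {
    int slot = (steps + d) % D;
    for (int ni : ring_hits[slot]) {
      double w = ring[(size_t)slot * n + ni];
      if (w != 0.0) { pd.push_back(d); pi.push_back(ni); pw.push_back(w); }
    }
  }
  NumericMatrix pend_out((int)pd.size(), 3);
  for (int k = 0; k < (int)pd.size(); ++k) {
    pend_out(k, 0) = pd[k]; pend_out(k, 1) = pi[k]; pend_out(k, 2) = pw[k];
  }

  return List::create(
    _["spike_step"] = IntegerVector(sp_step.begin(), sp_step.end()),
    _["spike_idx"]  = IntegerVector(sp_idx.begin(), sp_idx.end()),
    _["v"] = NumericVector(v.begin(), v.end()),
    _["a"] = NumericVector(a.begin(), a.end()),
    _["f"] = NumericVector(f.begin(), f.end()),
    _["r"] = IntegerVector(r.begin(), r.end()),
    _["pending"] = pend_out);
}
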