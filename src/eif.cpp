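#include <Rcpp.h>
using namespace Rcpp;

// Exponential integrate-and-fire membrane, forward Euler, units mV/pA/ms.
//
//   dV/dt = ( -(V - E_rest) + 0.001 * R * I + Delta_T * exp((V - V_T)/Delta_T) ) / tau
//   tau   = R * C / 1000   (MOhm * pF -> us, /1000 -> ms)
//
// Spike handling: integration proceeds until V crosses the cut-off
// V_T + 5*Delta_T; the trajectory is then rewound to the take-off sample
// (first sample at or above V_T since the last reset) and a stereotyped
// action-potential template, whose first sample equals V_T, is spliced in.
// Integration resumes from V_reset with the exponential term disabled for
// t_ref ms (absolute refractory period).  The take-off sample index is the
// ground-truth spike time.
//
// No randomness lives here: observation noise is added by the caller so all
// RNG goes through R's generator.
//
// [[Rcpp::export]]
List eif_integrate(NumericVector I, double dt, double C, double R,
                   double E_rest, double V_T, double Delta_T,
                   double V_reset, double t_ref, NumericVector tmpl,
                   double V0) {
  const int n = I.size();
  NumericVector V(n);
  std::vector<int> spikes;  // 0-based take-off indices
  const double tau = R * C / 1000.0;
  const double cutoff = V_T + 5.0 * Delta_T;
  const int ref_steps = (int)std::ceil(t_ref / dt);
  const int tlen = tmpl.size();

  double v = V0;
  int i = 0;
  int floor_idx = 0;      // earliest index a take-off search may reach
  int ref_until = 0;      // exponential term disabled below this index
  while (i < n) {
    V[i] = v;
    if (v >= cutoff && i >= ref_until) {
      // rewind to take-off: first sample >= V_T since floor_idx
      int take = i;
      while (take > floor_idx && V[take - 1] >= V_T) take--;
      spikes.push_back(take);
      int j = 0;
      for (; j < tlen && take + j < n; j++) V[take + j] = tmpl[j];
      i = take + j;               // first sample after the template
      v = V_reset;
      floor_idx = i;
      ref_until = i + ref_steps;
      continue;
    }
    double drive = -(v - E_rest) + 0.001 * R * I[i];
    if (i >= ref_until) {
      double x = (v - V_T) / Delta_T;
      if (x > 20.0) x = 20.0;     // overflow guard; cutoff fires first
      drive += Delta_T * std::exp(x);
    }
    v += dt * drive / tau;
    i++;
  }
  IntegerVector sp(spikes.size());
  for (size_t k = 0; k < spikes.size(); k++) sp[k] = spikes[k] + 1;  // 1-based
  return List::create(_["V"] = V, _["spike_idx"] = sp);
}

// Superpose scaled copies of a kernel onto a zero vector of length n:
// out[idx[k] .. idx[k]+len-1] += amp[k] * kernel.  idx is 1-based; events
// whose start falls outside [1, n] are clipped, not errors.
//
// [[Rcpp::export]]
NumericVector add_kernel_events(int n, IntegerVector idx, NumericVector amp,
                                NumericVector kernel) {
  NumericVector out(n);
  const int klen = kernel.size();
  for (int k = 0; k < idx.size(); k++) {
    int start = idx[k] - 1;
    for (int j = 0; j < klen; j++) {
      int p = start + j;
      if (p < 0) continue;
      if (p >= n) break;
      out[p] += amp[k] * kernel[j];
    }
  }
  return out;
}
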