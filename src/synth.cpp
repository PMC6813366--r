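#include <Rcpp.h>
using namespace Rcpp;

// Fused one-pass synthesis of voltage sweeps:
//   g_i  = phiSyn * g_{i-1} + quanta landing at sample i
//   vd_i = phiMem * vd_{i-1} + gain * g_i
//   x_i  = phiOu * x_{i-1} + w_i          (w holds pre-scaled innovations;
//                                          w_1 is the stationary start value)
//   v_i  = vRest + vd_i + x_i
// idx: 1-based sample index of each spike; amp: spikes x sweeps conductance.

// [[Rcpp::export]]
NumericMatrix cpp_synth_voltage(IntegerVector idx, NumericMatrix amp, int n,
                                double phiSyn, double phiMem, double gain,
                                NumericMatrix w, double phiOu, bool useNoise,
                                double vRest) {
  const int m = amp.ncol(), K = idx.size();
  NumericMatrix v(n, m);
  for (int j = 0; j < m; ++j) {
    double g = 0.0, vd = 0.0, x = 0.0;
    int k = 0;
    for (int i = 0; i < n; ++i) {
      g *= phiSyn;
      while (k < K && idx[k] == i + 1) { g += amp(k, j); ++k; }
      vd = phiMem * vd + gain * g;
      if (useNoise) x = phiOu * x + w(i, j);
      v(i, j) = vRest + vd + x;
    }
  }
  return v;
}

// Per-pulse amplitude: max over the post-stimulus window minus min over the
// pre-stimulus window, per column.  Window bounds are 1-based inclusive.

// [[Rcpp::export]]
NumericMatrix cpp_window_amplitudes(NumericMatrix v, IntegerVector preLo,
                                    IntegerVector preHi, IntegerVector postLo,
                                    IntegerVector postHi) {
  const int P = preLo.size(), m = v.ncol();
  NumericMatrix a(P, m);
  for (int j = 0; j < m; ++j) {
    for (int p = 0; p < P; ++p) {
      double mn = R_PosInf, mx = R_NegInf;
      for (int i = preLo[p] - 1; i < preHi[p]; ++i) mn = std::min(mn, v(i, j));
      for (int i = postLo[p] - 1; i < postHi[p]; ++i) mx = std::max(mx, v(i, j));
      a(p, j) = mx - mn;
    }
  }
  return a;
}
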