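#include <Rcpp.h>
using namespace Rcpp;

// Stream a piecewise-constant signal (per-event level, repeated for a
// per-event number of fine-grid steps) through a cascade of biquad
// sections (direct form II transposed) and decimate.  Streaming avoids
// materialising the fine grid, which can exceed 1e7 points.
//
// levels: per-event current level (pA)
// counts: per-event number of fine-grid steps (>= 0)
// sos:    n_sections x 5 matrix, columns b0 b1 b2 a1 a2 (a0 = 1)
// decim:  keep every decim-th filtered fine sample
// [[Rcpp::export]]
NumericVector sos_stream_cpp(const NumericVector& levels,
                             const NumericVector& counts,
                             const NumericMatrix& sos,
                             int decim) {
  const R_xlen_t n_ev = levels.size();
  if (counts.size() != n_ev) stop("levels/counts length mismatch");
  if (decim < 1) stop("decim must be >= 1");
  const int ns = sos.nrow();
  // start settled at the first level (the recording precedes the window);
  // DF2T steady state for unit-DC-gain sections
  std::vector<double> z1(ns, 0.0), z2(ns, 0.0);
  const double x0 = n_ev ? levels[0] : 0.0;
  for (int s = 0; s < ns; ++s) {
    z1[s] = (1.0 - sos(s, 0)) * x0;
    z2[s] = (sos(s, 2) - sos(s, 4)) * x0;
  }

  long long n_fine = 0;
  for (R_xlen_t e = 0; e < n_ev; ++e) n_fine += (long long)counts[e];
  const long long n_out = n_fine / decim;
  NumericVector out(n_out);

  long long step = 0, next_keep = decim - 1;
  R_xlen_t out_i = 0;
  for (R_xlen_t e = 0; e < n_ev; ++e) {
    const double level = levels[e];
    const long long run = (long long)counts[e];
    for (long long k = 0; k < run; ++k, ++step) {
      double x = level;
      for (int s = 0; s < ns; ++s) {
        const double y = sos(s, 0) * x + z1[s];
        z1[s] = sos(s, 1) * x - sos(s, 3) * y + z2[s];
        z2[s] = sos(s, 2) * x - sos(s, 4) * y;
        x = y;
      }
      if (step == next_keep) {
        out[out_i++] = x;
        next_keep += decim;
      }
    }
  }
  return out;
}
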