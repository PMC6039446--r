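#include <Rcpp.h>
using namespace Rcpp;

// Fused stochastic simulation + rendering of the O/S/M/F gating scheme:
// draws gating events with R's RNG (reproducible via set.seed on the R
// side), maps them onto the fine grid, streams each fine step through the
// biquad cascade and decimates -- without materialising the event
// sequence or the fine grid.  Used by the histogram fitter, where one
// minute of model time is simulated per objective evaluation.
//
// rates: k_OS, k_SO, k_OM, k_MO, k_OF, k_FO (1/s)
// [[Rcpp::export]]
NumericVector sim_render_cpp(const NumericVector& rates, double I_true,
                             double duration, double dt,
                             const NumericMatrix& sos, int decim) {
  if (rates.size() != 6) stop("need 6 gating rate constants");
  const double kOS = rates[0], kSO = rates[1], kOM = rates[2],
               kMO = rates[3], kOF = rates[4], kFO = rates[5];
  const double exitO = kOS + kOM + kOF;
  const long long n_fine = (long long)(duration / dt + 0.5);
  const long long n_out = n_fine / decim;
  const int ns = sos.nrow();
  if (n_fine <= 0) stop("empty trace");

  if (exitO > 0) {   // expected event count guard
    double mean_cycle = 1.0 / exitO;
    if (kOS > 0 && kSO > 0) mean_cycle += (kOS / exitO) / kSO;
    if (kOM > 0 && kMO > 0) mean_cycle += (kOM / exitO) / kMO;
    if (kOF > 0 && kFO > 0) mean_cycle += (kOF / exitO) / kFO;
    if (duration / mean_cycle > 5e7)
      stop("scheme too fast: more than 5e7 expected gating events");
  }

  RNGScope scope;
  NumericVector out(n_out);
  std::vector<double> z1(ns), z2(ns);
  for (int s = 0; s < ns; ++s) {           // start settled at I_true (in O)
    z1[s] = (1.0 - sos(s, 0)) * I_true;
    z2[s] = (sos(s, 2) - sos(s, 4)) * I_true;
  }

  double t = 0.0;                          // continuous event clock
  long long step = 0, next_keep = decim - 1;
  R_xlen_t out_i = 0;
  bool open = true;
  double closed_back = 0.0;                // return rate of the next sojourn
  while (step < n_fine) {
    double level, dwell;
    if (open) {
      level = I_true;
      dwell = exitO > 0 ? R::rexp(1.0 / exitO) : R_PosInf;
    } else {
      level = 0.0;
      dwell = closed_back > 0 ? R::rexp(1.0 / closed_back) : R_PosInf;
    }
    long long boundary = n_fine;
    if (R_FINITE(dwell)) {
      t += dwell;
      boundary = (long long)(t / dt + 0.5);
      if (boundary > n_fine) boundary = n_fine;
    }
    if (ns == 2) {      // unrolled fast path for the 4-pole cascade
      const double b00 = sos(0,0), b01 = sos(0,1), b02 = sos(0,2),
                   a01 = sos(0,3), a02 = sos(0,4),
                   b10 = sos(1,0), b11 = sos(1,1), b12 = sos(1,2),
                   a11 = sos(1,3), a12 = sos(1,4);
      double u1 = z1[0], u2 = z2[0], v1 = z1[1], v2 = z2[1];
      for (; step < boundary; ++step) {
        const double y0 = b00 * level + u1;
        u1 = b01 * level - a01 * y0 + u2;
        u2 = b02 * level - a02 * y0;
        const double y1 = b10 * y0 + v1;
        v1 = b11 * y0 - a11 * y1 + v2;
        v2 = b12 * y0 - a12 * y1;
        if (step == next_keep) { out[out_i++] = y1; next_keep += decim; }
      }
      z1[0] = u1; z2[0] = u2; z1[1] = v1; z2[1] = v2;
    } else {
      for (; step < boundary; ++step) {
        double x = level;
        for (int s = 0; s < ns; ++s) {
          const double y = sos(s, 0) * x + z1[s];
          z1[s] = sos(s, 1) * x - sos(s, 3) * y + z2[s];
          z2[s] = sos(s, 2) * x - sos(s, 4) * y;
          x = y;
        }
        if (step == next_keep) { out[out_i++] = x; next_keep += decim; }
      }
    }
    if (!R_FINITE(dwell)) break;           // absorbed until the window end
    if (open) {                            // choose the sink state
      const double u = unif_rand() * exitO;
      if (u < kOS) closed_back = kSO;
      else if (u < kOS + kOM) closed_back = kMO;
      else closed_back = kFO;
    }
    open = !open;
  }
  return out;
}
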