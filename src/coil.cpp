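#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Magnetic vector potential rate dA/dt of a set of straight current segments,
// using the closed-form line integral of 1/distance along each segment:
//   int dl' / |r - r'| = log((d1 + d2 + L) / (d1 + d2 - L))
// with d1, d2 the distances from the evaluation point to the segment ends and
// L the segment length.  The log ratio is dimensionless, so millimetre inputs
// are fine; mu0/4pi = 1e-7 T m/A gives the field in V/m directly.
//
// Evaluation points closer to a wire than `guard` (mm) have the denominator
// clamped; the number of clamped points is returned in attribute "n_clamped".

// [[Rcpp::export]]
NumericMatrix cpp_dadt(NumericMatrix segments, NumericMatrix pts,
                       double didt, double guard) {
  const int ns = segments.nrow(), np = pts.nrow();
  NumericMatrix out(np, 3);
  const double k = 1e-7 * didt;
  int n_clamped = 0;

  std::vector<double> ux(ns), uy(ns), uz(ns), len(ns);
  for (int s = 0; s < ns; ++s) {
    const double ax = segments(s, 3) - segments(s, 0);
    const double ay = segments(s, 4) - segments(s, 1);
    const double az = segments(s, 5) - segments(s, 2);
    const double L = std::sqrt(ax * ax + ay * ay + az * az);
    len[s] = L;
    ux[s] = ax / L; uy[s] = ay / L; uz[s] = az / L;
  }

  for (int p = 0; p < np; ++p) {
    const double x = pts(p, 0), y = pts(p, 1), z = pts(p, 2);
    double sx = 0.0, sy = 0.0, sz = 0.0;
    bool clamped = false;
    for (int s = 0; s < ns; ++s) {
      const double d1x = x - segments(s, 0), d1y = y - segments(s, 1), d1z = z - segments(s, 2);
      const double d2x = x - segments(s, 3), d2y = y - segments(s, 4), d2z = z - segments(s, 5);
      const double d1 = std::sqrt(d1x * d1x + d1y * d1y + d1z * d1z);
      const double d2 = std::sqrt(d2x * d2x + d2y * d2y + d2z * d2z);
      double denom = d1 + d2 - len[s];
      if (denom < guard) { denom = guard; clamped = true; }
      const double w = std::log((d1 + d2 + len[s]) / denom);
      sx += ux[s] * w; sy += uy[s] * w; sz += uz[s] * w;
    }
    out(p, 0) = k * sx; out(p, 1) = k * sy; out(p, 2) = k * sz;
    if (clamped) ++n_clamped;
  }
  out.attr("n_clamped") = n_clamped;
  return out;
}
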