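#ifndef MARKQG_TRUNCNORM_H
#define MARKQG_TRUNCNORM_H

#include <Rmath.h>
#include <cmath>
#include <algorithm>

// Standard-normal draw truncated to (a, b), robust in far tails.
// Inverse-CDF in the central region; Robert (1995) exponential rejection
// for one-sided tails beyond ~5.5 sd. Never returns NaN/Inf for finite
// category intervals: degenerate intervals collapse to the nearest bound.
inline double rtnorm_std(double a, double b) {
  const double tail = 5.5;
  if (a > b) std::swap(a, b);
  if (a > tail || b < -tail) {
    // far one-sided tail; sample lower-truncated tail and reflect if needed
    bool flip = (b < -tail);
    double lo = flip ? -b : a;
    double hi = flip ? -a : b;
    // Robert's translated-exponential rejection for x >= lo
    double alpha = 0.5 * (lo + std::sqrt(lo * lo + 4.0));
    for (int it = 0; it < 1000; ++it) {
      double z = lo + ::exp_rand() / alpha;
      if (z > hi) continue;
      double rho = std::exp(-0.5 * (z - alpha) * (z - alpha));
      if (::unif_rand() <= rho) return flip ? -z : z;
    }
    // numerically degenerate interval: clamp just inside the near bound
    double z = std::min(hi, lo + 1e-8);
    return flip ? -z : z;
  }
  double pa = ::Rf_pnorm5(a, 0.0, 1.0, 1, 0);
  double pb = ::Rf_pnorm5(b, 0.0, 1.0, 1, 0);
  if (pb - pa < 1e-14) {
    // interval carries no mass at double precision: midpoint of the
    // clipped interval keeps the draw inside its category
    double lo = std::max(a, -tail), hi = std::min(b, tail);
    if (lo > hi) { lo = a; hi = b; }
    return 0.5 * (lo + hi);
  }
  double u = pa + ::unif_rand() * (pb - pa);
  double z = ::Rf_qnorm5(u, 0.0, 1.0, 1, 0);
  return std::min(std::max(z, a), b);
}

inline double rtnorm(double mean, double sd, double lo, double hi) {
  double a = (lo - mean) / sd, b = (hi - mean) / sd;
  return mean + sd * rtnorm_std(a, b);
}

#endif
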