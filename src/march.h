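#ifndef MEMDYN_MARCH_H
#define MEMDYN_MARCH_H

#include <cmath>

// shared pieces of the exponential-midpoint integrator

static inline double md_phi1(double z) {
  if (std::fabs(z) < 1e-8) return 1.0 + 0.5 * z;
  return std::expm1(z) / z;
}

static inline double md_step(double x, double h,
                             double a0, double a1,
                             double b0, double b1) {
  const double am = 0.5 * (a0 + a1);
  const double bm = 0.5 * (b0 + b1);
  const double z = -am * h;
  const double e = std::expm1(z);
  const double p1 = (std::fabs(z) < 1e-8) ? 1.0 + 0.5 * z : e / z;
  return x * (e + 1.0) + h * bm * p1;
}

static inline double md_lin(const double *t, const double *v, int i, double s) {
  const double w = (s - t[i]) / (t[i + 1] - t[i]);
  return v[i] + w * (v[i + 1] - v[i]);
}

static inline int md_lower_index(const double *t, int m, double s) {
  int lo = 0, hi = m - 1;
  while (hi - lo > 1) {
    int mid = (lo + hi) / 2;
    if (t[mid] <= s) lo = mid; else hi = mid;
  }
  if (lo > m - 2) lo = m - 2;
  return lo;
}

#endif
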