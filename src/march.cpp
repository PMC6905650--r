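#include <Rcpp.h>
#include "march.h"
using namespace Rcpp;

// Exponential-midpoint integrator for scalar linear ODEs of the form
//   x'(t) = b(t) - a(t) x(t)
// sampled on a (not necessarily uniform) time grid. The step is exact for
// constant coefficients and second-order accurate for smoothly varying ones,
// and is unconditionally stable for a > 0 -- loss rates in these models span
// ~1e-5 to ~10 per day, so explicit RK stepping at day-scale steps would not be.

// [[Rcpp::export]]
NumericVector march_affine_path(NumericVector t, NumericVector a,
                                NumericVector b, double x0) {
  const int m = t.size();
  NumericVector x(m);
  x[0] = x0;
  for (int i = 0; i + 1 < m; ++i) {
    x[i + 1] = md_step(x[i], t[i + 1] - t[i], a[i], a[i + 1], b[i], b[i + 1]);
  }
  return x;
}

// March x' = b_j(t) - a(t) x from x(t_start[j]) = 0 to t_end[j], for each
// column j of B. Used for per-mouse chimerism marches: every mouse shares the
// per-capita rate a(t) but has its own forcing (source chimerism is a function
// of time since its own BMT).
// [[Rcpp::export]]
NumericVector march_affine_at(NumericVector t, NumericVector a, NumericMatrix B,
                              NumericVector t_start, NumericVector t_end) {
  const int J = t_start.size();
  const int m = t.size();
  const double *tp = t.begin();
  const double *ap = a.begin();
  NumericVector out(J);
  for (int j = 0; j < J; ++j) {
    const double ts = t_start[j], te = t_end[j];
    if (te <= ts) { out[j] = 0.0; continue; }
    if (ts < tp[0] - 1e-9 || te > tp[m - 1] + 1e-9)
      stop("march_affine_at: start/end outside grid");
    const double *bp = &B(0, j);
    int i = md_lower_index(tp, m, ts);
    double x = 0.0;
    double a0 = md_lin(tp, ap, i, ts);
    double b0 = md_lin(tp, bp, i, ts);
    double tcur = ts;
    while (tcur < te - 1e-12) {
      double tnext, a1, b1;
      if (i + 1 < m - 1 && tp[i + 1] < te) {
        tnext = tp[i + 1]; a1 = ap[i + 1]; b1 = bp[i + 1]; ++i;
      } else {
        tnext = te;
        a1 = md_lin(tp, ap, i, te);
        b1 = md_lin(tp, bp, i, te);
      }
      x = md_step(x, tnext - tcur, a0, a1, b0, b1);
      tcur = tnext; a0 = a1; b0 = b1;
    }
    out[j] = x;
  }
  return out;
}

// Chained pair of linear ODEs used by the two-phase model's chimerism:
//   xf' = bf_j(t) - af(t) xf          (fast subset, forced by source chimerism)
//   xs' = as(t) * xf - as(t) xs       (slow subset, forced by fast chimerism)
// Both start at zero at t_start[j]; values of (xf, xs) at t_end[j] returned.
// [[Rcpp::export]]
NumericMatrix march_two_at(NumericVector t, NumericVector af, NumericMatrix Bf,
                           NumericVector as, NumericVector t_start,
                           NumericVector t_end) {
  const int J = t_start.size();
  const int m = t.size();
  const double *tp = t.begin();
  const double *afp = af.begin();
  const double *asp = as.begin();
  NumericMatrix out(J, 2);
  for (int j = 0; j < J; ++j) {
    const double ts = t_start[j], te = t_end[j];
    if (te <= ts) { out(j, 0) = 0.0; out(j, 1) = 0.0; continue; }
    if (ts < tp[0] - 1e-9 || te > tp[m - 1] + 1e-9)
      stop("march_two_at: start/end outside grid");
    const double *bfp = &Bf(0, j);
    int i = md_lower_index(tp, m, ts);
    double xf = 0.0, xs = 0.0;
    double af0 = md_lin(tp, afp, i, ts);
    double bf0 = md_lin(tp, bfp, i, ts);
    double as0 = md_lin(tp, asp, i, ts);
    double tcur = ts;
    while (tcur < te - 1e-12) {
      double tnext, af1, bf1, as1;
      if (i + 1 < m - 1 && tp[i + 1] < te) {
        tnext = tp[i + 1]; af1 = afp[i + 1]; bf1 = bfp[i + 1]; as1 = asp[i + 1];
        ++i;
      } else {
        tnext = te;
        af1 = md_lin(tp, afp, i, te);
        bf1 = md_lin(tp, bfp, i, te);
        as1 = md_lin(tp, asp, i, te);
      }
      const double h = tnext - tcur;
      const double xf_new = md_step(xf, h, af0, af1, bf0, bf1);
      // slow subset: forcing as(t) * xf(t), using the just-computed xf endpoints
      xs = md_step(xs, h, as0, as1, as0 * xf, as1 * xf_new);
      xf = xf_new;
      tcur = tnext; af0 = af1; bf0 = bf1; as0 = as1;
    }
    out(j, 0) = xf;
    out(j, 1) = xs;
  }
  return out;
}
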