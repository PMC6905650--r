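#include <Rcpp.h>
#include "march.h"
using namespace Rcpp;

// Profiled negative log-likelihoods of the four memory models, evaluated
// entirely in compiled code. These are the optimisation objectives used by
// fit_model() and bootstrap_ci(); the R-level predict_cohort() methods are
// the reference implementation and the two are checked against each other in
// the test suite.
//
// Conventions shared with the R engine:
//  * tt is a fine grid from the baseline age t0 to the last observation;
//  * S is the source size on tt; CHI is the per-mouse normalised source
//    chimerism on tt (a function of time since each mouse's BMT);
//  * each mouse contributes x = log(count), y = asin(sqrt(chi_norm));
//  * ln L = -(n/2) ln(SSRx * SSRy) - 2n after profiling the error variances.

static const double BIG = 1e10;
static const double SSR_FLOOR = 1e-30;

static double negll_value(int n, double ssr_x, double ssr_y) {
  double sx = ssr_x > SSR_FLOOR ? ssr_x : SSR_FLOOR;
  double sy = ssr_y > SSR_FLOOR ? ssr_y : SSR_FLOOR;
  double ll = -(n / 2.0) * std::log(sx * sy) - 2.0 * n;
  if (!std::isfinite(ll)) return BIG;
  return -ll;
}

static double interp1(const double *tp, const double *v, int m, double s) {
  int i = md_lower_index(tp, m, s);
  return md_lin(tp, v, i, s);
}

// march x' = b(t) - a x with constant a and grid forcing b, from x(t0) = x0
static bool path_const_a(const double *tp, int m, double a, const double *b,
                         double x0, double *out) {
  out[0] = x0;
  for (int i = 0; i + 1 < m; ++i) {
    out[i + 1] = md_step(out[i], tp[i + 1] - tp[i], a, a, b[i], b[i + 1]);
    if (!std::isfinite(out[i + 1])) return false;
  }
  return true;
}

// chimerism march for one mouse: x' = k(t) (chi_s(t) - x) from ts (x = 0)
// to te, with k and chi_s sampled on the grid
static double chi_march(const double *tp, int m, const double *k,
                        const double *cs, double ts, double te) {
  if (te <= ts) return 0.0;
  int i = md_lower_index(tp, m, ts);
  double a0 = md_lin(tp, k, i, ts);
  double b0 = md_lin(tp, cs, i, ts) * a0;
  double x = 0.0, tcur = ts;
  while (tcur < te - 1e-12) {
    double tnext, a1, b1;
    if (i + 1 < m - 1 && tp[i + 1] < te) {
      tnext = tp[i + 1]; a1 = k[i + 1]; b1 = cs[i + 1] * a1; ++i;
    } else {
      tnext = te;
      a1 = md_lin(tp, k, i, te);
      b1 = md_lin(tp, cs, i, te) * a1;
    }
    x = md_step(x, tnext - tcur, a0, a1, b0, b1);
    tcur = tnext; a0 = a1; b0 = b1;
  }
  return x;
}

// march x' = b(t) - a x with constant a, from x(ts) = 0 to te
static double march_forced(const double *tp, int m, double a, const double *b,
                           double ts, double te) {
  if (te <= ts) return 0.0;
  int i = md_lower_index(tp, m, ts);
  double b0 = md_lin(tp, b, i, ts);
  double x = 0.0, tcur = ts;
  while (tcur < te - 1e-12) {
    double tnext, b1;
    if (i + 1 < m - 1 && tp[i + 1] < te) {
      tnext = tp[i + 1]; b1 = b[i + 1]; ++i;
    } else {
      tnext = te;
      b1 = md_lin(tp, b, i, te);
    }
    x = md_step(x, tnext - tcur, a, a, b0, b1);
    tcur = tnext; b0 = b1;
  }
  return x;
}

static double clip01(double v) {
  if (v < 0.0) return 0.0;
  if (v > 1.0) return 1.0;
  return v;
}

// [[Rcpp::export]]
double negll_homog_cpp(NumericVector par, NumericVector tt, NumericVector S,
                       NumericMatrix CHI, NumericVector t_start,
                       NumericVector obs_age, NumericVector x,
                       NumericVector y) {
  const double M0 = par[0], phi = par[1], lam = par[2];
  if (!std::isfinite(M0) || !std::isfinite(phi) || !std::isfinite(lam) ||
      M0 <= 0.0 || phi < 0.0)
    return BIG;
  const int m = tt.size(), n = t_start.size();
  const double *tp = tt.begin();
  std::vector<double> b(m), M(m), k(m);
  for (int i = 0; i < m; ++i) b[i] = phi * S[i];
  if (!path_const_a(tp, m, lam, b.data(), M0, M.data())) return BIG;
  for (int i = 0; i < m; ++i) {
    if (M[i] <= 0.0) return BIG;
    k[i] = phi * S[i] / M[i];
  }
  double ssr_x = 0.0, ssr_y = 0.0;
  for (int j = 0; j < n; ++j) {
    double Mo = interp1(tp, M.data(), m, obs_age[j]);
    double ch = chi_march(tp, m, k.data(), &CHI(0, j), t_start[j], obs_age[j]);
    double X = std::log(Mo);
    double Y = std::asin(std::sqrt(clip01(ch)));
    if (!std::isfinite(X) || !std::isfinite(Y)) return BIG;
    ssr_x += (x[j] - X) * (x[j] - X);
    ssr_y += (y[j] - Y) * (y[j] - Y);
  }
  return negll_value(n, ssr_x, ssr_y);
}

// [[Rcpp::export]]
double negll_resistant_cpp(NumericVector par, NumericVector tt,
                           NumericVector S, NumericMatrix CHI,
                           NumericVector t_start, NumericVector obs_age,
                           NumericVector x, NumericVector y) {
  const double M0 = par[0], I0 = par[1], phi = par[2], lam = par[3];
  if (!std::isfinite(M0) || !std::isfinite(I0) || !std::isfinite(phi) ||
      !std::isfinite(lam) || M0 < 0.0 || I0 < 0.0 || phi < 0.0)
    return BIG;
  const int m = tt.size(), n = t_start.size();
  const double *tp = tt.begin();
  std::vector<double> b(m), Md(m);
  for (int i = 0; i < m; ++i) b[i] = phi * S[i];
  if (!path_const_a(tp, m, lam, b.data(), M0, Md.data())) return BIG;
  // donor numbers (normalised): x' = phi chi_s(t) S(t) - lam x
  double ssr_x = 0.0, ssr_y = 0.0;
  std::vector<double> bd(m);
  for (int j = 0; j < n; ++j) {
    double Mtot = interp1(tp, Md.data(), m, obs_age[j]) + I0;
    if (Mtot <= 0.0) return BIG;
    const double *cj = &CHI(0, j);
    for (int i = 0; i < m; ++i) bd[i] = phi * S[i] * cj[i];
    double Dn = march_forced(tp, m, lam, bd.data(), t_start[j], obs_age[j]);
    double X = std::log(Mtot);
    double Y = std::asin(std::sqrt(clip01(Dn / Mtot)));
    if (!std::isfinite(X) || !std::isfinite(Y)) return BIG;
    ssr_x += (x[j] - X) * (x[j] - X);
    ssr_y += (y[j] - Y) * (y[j] - Y);
  }
  return negll_value(n, ssr_x, ssr_y);
}

// [[Rcpp::export]]
double negll_two_phase_cpp(NumericVector par, NumericVector tt,
                           NumericVector S, NumericMatrix CHI,
                           NumericVector t_start, NumericVector obs_age,
                           NumericVector x, NumericVector y) {
  // par = Mslow0, phi, lam_fast, lam_slow, gamma, Mfast0 (NA => QE init)
  const double Ms0 = par[0], phi = par[1], lf = par[2], ls = par[3],
               g = par[4];
  if (!std::isfinite(Ms0) || !std::isfinite(phi) || !std::isfinite(lf) ||
      !std::isfinite(ls) || !std::isfinite(g) || Ms0 < 0.0 || phi < 0.0 ||
      g < 0.0 || lf + g <= 0.0)
    return BIG;
  const int m = tt.size(), n = t_start.size();
  const double *tp = tt.begin();
  double Mf0 = ISNAN(par[5]) ? phi * S[0] / (lf + g) : par[5];
  if (!std::isfinite(Mf0) || Mf0 <= 0.0) return BIG;
  std::vector<double> b(m), Mf(m), Ms(m), kf(m), ks(m);
  for (int i = 0; i < m; ++i) b[i] = phi * S[i];
  if (!path_const_a(tp, m, lf + g, b.data(), Mf0, Mf.data())) return BIG;
  for (int i = 0; i < m; ++i) b[i] = g * Mf[i];
  if (!path_const_a(tp, m, ls, b.data(), Ms0, Ms.data())) return BIG;
  for (int i = 0; i < m; ++i) {
    if (Mf[i] <= 0.0 || Ms[i] < 0.0 || Mf[i] + Ms[i] <= 0.0) return BIG;
    kf[i] = phi * S[i] / Mf[i];
    ks[i] = g * Mf[i] / (Ms[i] > 1e-12 ? Ms[i] : 1e-12);
  }
  double ssr_x = 0.0, ssr_y = 0.0;
  for (int j = 0; j < n; ++j) {
    const double ts = t_start[j], te = obs_age[j];
    const double *cj = &CHI(0, j);
    double xf = 0.0, xs = 0.0;
    if (te > ts) {
      int i = md_lower_index(tp, m, ts);
      double af0 = md_lin(tp, kf.data(), i, ts);
      double bf0 = md_lin(tp, cj, i, ts) * af0;
      double as0 = md_lin(tp, ks.data(), i, ts);
      double tcur = ts;
      while (tcur < te - 1e-12) {
        double tnext, af1, bf1, as1;
        if (i + 1 < m - 1 && tp[i + 1] < te) {
          tnext = tp[i + 1]; af1 = kf[i + 1]; bf1 = cj[i + 1] * af1;
          as1 = ks[i + 1]; ++i;
        } else {
          tnext = te;
          af1 = md_lin(tp, kf.data(), i, te);
          bf1 = md_lin(tp, cj, i, te) * af1;
          as1 = md_lin(tp, ks.data(), i, te);
        }
        const double h = tnext - tcur;
        const double xf_new = md_step(xf, h, af0, af1, bf0, bf1);
        xs = md_step(xs, h, as0, as1, as0 * xf, as1 * xf_new);
        xf = xf_new;
        tcur = tnext; af0 = af1; bf0 = bf1; as0 = as1;
      }
    }
    double Mfo = interp1(tp, Mf.data(), m, te);
    double Mso = interp1(tp, Ms.data(), m, te);
    double tot = Mfo + Mso;
    double ch = (xf * Mfo + xs * Mso) / tot;
    double X = std::log(tot);
    double Y = std::asin(std::sqrt(clip01(ch)));
    if (!std::isfinite(X) || !std::isfinite(Y)) return BIG;
    ssr_x += (x[j] - X) * (x[j] - X);
    ssr_y += (y[j] - Y) * (y[j] - Y);
  }
  return negll_value(n, ssr_x, ssr_y);
}

// cumulative integral of the age-dependent loss rate on a uniform fine grid
// (trapezoid at step ha; the integrand is smooth and slowly varying)
struct LamCum {
  double ha;
  std::vector<double> L;
  void build(double lam0, double A, int nexp, bool exponential, double amax,
             double ha_) {
    ha = ha_;
    int m = (int)std::ceil(amax / ha) + 2;
    L.resize(m);
    L[0] = 0.0;
    double prev = lam0; // lambda(0)
    for (int i = 1; i < m; ++i) {
      double a = i * ha;
      double cur;
      if (exponential) cur = lam0 * std::exp(-a / A);
      else cur = lam0 / (1.0 + std::pow(a / A, (double)nexp));
      L[i] = L[i - 1] + 0.5 * ha * (prev + cur);
      prev = cur;
    }
  }
  double operator()(double a) const {
    if (a <= 0.0) return 0.0;
    double u = a / ha;
    int i = (int)u;
    if (i + 1 >= (int)L.size()) i = (int)L.size() - 2;
    double w = u - i;
    return L[i] + w * (L[i + 1] - L[i]);
  }
};

// [[Rcpp::export]]
double negll_age_dep_cpp(NumericVector par, int nexp, bool exponential,
                         double t0, double S_t0,
                         NumericVector gw, NumericVector a0,
                         NumericVector d, NumericMatrix Snew, NumericMatrix Ad,
                         NumericVector L, NumericMatrix SN, NumericMatrix CN,
                         NumericMatrix AL,
                         NumericVector x, NumericVector y) {
  // par = phi, p, lam0, A
  const double phi = par[0], p = par[1], lam0 = par[2], A = par[3];
  if (!std::isfinite(phi) || !std::isfinite(p) || !std::isfinite(lam0) ||
      !std::isfinite(A) || phi < 0.0 || A <= 0.0)
    return BIG;
  const int K = gw.size(), n = d.size();
  double amax = t0;
  for (int j = 0; j < n; ++j) if (t0 + d[j] > amax) amax = t0 + d[j];
  LamCum Lam;
  Lam.build(lam0, A, nexp, exponential, amax, 0.05);

  std::vector<double> g0(K), L0(K);
  for (int k = 0; k < K; ++k) {
    g0[k] = phi * S_t0 * std::exp(p * a0[k]);
    L0[k] = Lam(a0[k]);
  }
  double ssr_x = 0.0, ssr_y = 0.0;
  for (int j = 0; j < n; ++j) {
    double Minit = 0.0, Mnew = 0.0, Dn = 0.0;
    for (int k = 0; k < K; ++k) {
      Minit += gw[k] * g0[k] * std::exp(L0[k] - Lam(a0[k] + d[j]));
      Mnew += gw[k] * Snew(k, j) * std::exp(-Lam(Ad(k, j)));
      Dn += gw[k] * SN(k, j) * CN(k, j) * std::exp(-Lam(AL(k, j)));
    }
    double M = t0 * Minit + phi * d[j] * Mnew;
    if (!std::isfinite(M) || M <= 0.0) return BIG;
    double ch = phi * L[j] * Dn / M;
    double X = std::log(M);
    double Y = std::asin(std::sqrt(clip01(ch)));
    if (!std::isfinite(X) || !std::isfinite(Y)) return BIG;
    ssr_x += (x[j] - X) * (x[j] - X);
    ssr_y += (y[j] - Y) * (y[j] - Y);
  }
  return negll_value(n, ssr_x, ssr_y);
}
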