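// Kolmogorov-Smirnov x_min scans for continuous power-law and log-normal
// tail fits.  Candidates are the distinct observed values; per candidate the
// shape parameters are the exact MLE on the tail above it and D is the KS
// distance between the tail empirical CDF and the fitted model.  These scans
// sit inside a 50-replicate bootstrap, hence the compiled implementation.

#include <Rcpp.h>
using namespace Rcpp;

// hazard of the standard normal, stable for large z
static double norm_hazard(double z) {
  return std::exp(R::dnorm(z, 0.0, 1.0, 1) - R::pnorm(z, 0.0, 1.0, 0, 1));
}

// Left-truncated normal MLE via exponential-family moment matching:
// with z = (t - mu)/sigma and h = hazard(z),
//   E[Y]  = mu + sigma h(z),  Var[Y] = sigma^2 (1 + z h - h^2).
// Matching sample mean m1 and (n-denominator) variance v and eliminating
// (mu, sigma) leaves the scalar root problem g(z) = sigma(z)(z - h(z)) -
// (t - m1) = 0, solved by bisection.  Returns false on degenerate input.
// The upper bound on z is an identifiability constraint: fits with the
// truncation point more than 3 log-sd above the log-mean describe a
// lognormal whose entire body is unobserved and can mimic any power law;
// capping z keeps the family honest while leaving genuine lognormal tails
// (z well below 0 in practice) untouched.
static bool trunc_norm_mle(double m1, double v, double t,
                           double &mu, double &sigma) {
  if (!(v > 0.0)) return false;
  const double lo0 = -15.0, hi0 = 3.0;
  auto g = [&](double z) {
    double h = norm_hazard(z);
    double denom = 1.0 + z * h - h * h;
    if (denom <= 1e-14) denom = 1e-14;
    double s = std::sqrt(v / denom);
    return s * (z - h) - (t - m1);
  };
  double lo = lo0, hi = hi0;
  double glo = g(lo), ghi = g(hi);
  double z;
  if (glo > 0.0) z = lo;        // effectively untruncated
  else if (ghi < 0.0) z = hi;   // near-exponential boundary fit
  else {
    for (int it = 0; it < 200; ++it) {
      z = 0.5 * (lo + hi);
      double gm = g(z);
      if (gm < 0.0) lo = z; else hi = z;
      if (hi - lo < 1e-12) break;
    }
    z = 0.5 * (lo + hi);
  }
  double h = norm_hazard(z);
  double denom = 1.0 + z * h - h * h;
  if (denom <= 1e-14) denom = 1e-14;
  sigma = std::sqrt(v / denom);
  mu = m1 - sigma * h;
  return R_finite(mu) && R_finite(sigma) && sigma > 0.0;
}

// [[Rcpp::export]]
List cpp_trunc_lnorm_mle(NumericVector y_tail, double t) {
  int n = y_tail.size();
  double m1 = 0.0, m2 = 0.0;
  for (int i = 0; i < n; ++i) m1 += y_tail[i];
  m1 /= n;
  for (int i = 0; i < n; ++i) m2 += (y_tail[i] - m1) * (y_tail[i] - m1);
  double v = m2 / n;
  double mu = NA_REAL, sigma = NA_REAL;
  bool ok = trunc_norm_mle(m1, v, t, mu, sigma);
  return List::create(_["meanlog"] = mu, _["sdlog"] = sigma, _["ok"] = ok);
}

// KS distance of a sorted tail sample against a model CDF already evaluated
// at the sample points (F monotone).  Standard two-sided step comparison.
static double ks_dist(const std::vector<double> &F) {
  int m = F.size();
  double D = 0.0;
  for (int j = 0; j < m; ++j) {
    double lo = std::fabs(F[j] - (double)j / m);
    double hi = std::fabs(F[j] - (double)(j + 1) / m);
    if (lo > D) D = lo;
    if (hi > D) D = hi;
  }
  return D;
}

// [[Rcpp::export]]
List cpp_pl_scan(NumericVector x_sorted, int min_tail) {
  int n = x_sorted.size();
  std::vector<double> lnx(n);
  for (int i = 0; i < n; ++i) lnx[i] = std::log(x_sorted[i]);
  // suffix sums of ln x
  std::vector<double> suf(n + 1, 0.0);
  for (int i = n - 1; i >= 0; --i) suf[i] = suf[i + 1] + lnx[i];

  std::vector<double> xm, al, Dv; std::vector<int> nt;
  std::vector<double> F;
  for (int i = 0; i < n; ++i) {
    if (i > 0 && x_sorted[i] == x_sorted[i - 1]) continue; // distinct values
    int m = n - i;
    if (m < min_tail) break;
    double xmin = x_sorted[i];
    double slog = suf[i] - m * lnx[i];
    if (slog <= 0.0) continue; // all tail values equal
    double alpha = 1.0 + m / slog;
    F.assign(m, 0.0);
    for (int j = 0; j < m; ++j)
      F[j] = 1.0 - std::pow(x_sorted[i + j] / xmin, 1.0 - alpha);
    xm.push_back(xmin); al.push_back(alpha);
    Dv.push_back(ks_dist(F)); nt.push_back(m);
  }
  return List::create(_["xmin"] = xm, _["alpha"] = al, _["D"] = Dv,
                      _["n_tail"] = nt);
}

// [[Rcpp::export]]
List cpp_ln_scan(NumericVector x_sorted, int min_tail) {
  int n = x_sorted.size();
  std::vector<double> y(n);
  for (int i = 0; i < n; ++i) y[i] = std::log(x_sorted[i]);
  std::vector<double> suf1(n + 1, 0.0), suf2(n + 1, 0.0);
  for (int i = n - 1; i >= 0; --i) {
    suf1[i] = suf1[i + 1] + y[i];
    suf2[i] = suf2[i + 1] + y[i] * y[i];
  }
  std::vector<double> xm, muv, sgv, Dv; std::vector<int> nt;
  std::vector<double> F;
  for (int i = 0; i < n; ++i) {
    if (i > 0 && x_sorted[i] == x_sorted[i - 1]) continue;
    int m = n - i;
    if (m < min_tail) break;
    double t = y[i];
    double m1 = suf1[i] / m;
    double v = suf2[i] / m - m1 * m1;
    double mu, sigma;
    if (!trunc_norm_mle(m1, v, t, mu, sigma)) continue;
    double St = R::pnorm(t, mu, sigma, 0, 0);  // survival at the cutoff
    if (St <= 0.0) continue;
    F.assign(m, 0.0);
    for (int j = 0; j < m; ++j)
      F[j] = 1.0 - R::pnorm(y[i + j], mu, sigma, 0, 0) / St;
    xm.push_back(x_sorted[i]); muv.push_back(mu); sgv.push_back(sigma);
    Dv.push_back(ks_dist(F)); nt.push_back(m);
  }
  return List::create(_["xmin"] = xm, _["meanlog"] = muv, _["sdlog"] = sgv,
                      _["D"] = Dv, _["n_tail"] = nt);
}
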