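// Analytic hazard kernel for the field-defect + two-stage clonal expansion
// model.  The convolution over the field-defect onset age is evaluated with
// fixed-order Gauss-Legendre panels split at the integrand's kink locations
// (the attenuation threshold s0 and the calendar reference crossing y0 - B);
// the cumulative field-defect hazard is precomputed per cohort by composite
// Simpson integration on a dense grid and interpolated linearly.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

struct TrendC {
  double w1, w2, y0, s0, b1, b2;
  bool atten, cap;
};

// Regularized field-defect rate nu_FD(s; B).  For B >= y0 the rate equals
// nu0 exactly (period and cohort trends vanish and the age attenuation is
// dropped); for B < y0 the period factor is 1 once y = B + s >= y0 while the
// cohort factor and the log(s/s0) attenuation still apply.
inline double nu_fd_eval(double s, double B, double nu0, const TrendC &tr) {
  if (B >= tr.y0) return nu0;
  double A = 1.0;
  if (tr.atten) {
    if (s <= tr.s0) return 0.0;
    A = std::log(s / tr.s0);
    if (tr.cap && A > 1.0) A = 1.0;
  }
  double y = B + s;
  double P = 1.0;
  if (y < tr.y0) {
    double x = y - tr.y0;
    P = std::exp(tr.w1 * x * x * (1.0 + tr.w2 * x));
  }
  double xb = B - tr.y0;
  double C = std::exp(tr.b1 * xb * xb * (1.0 + tr.b2 * xb));
  return nu0 * P * C * A;
}

// Roots of the two-stage characteristic quadratic, computed in the stable
// (g, mu2) combination: p + q = -g, p q = -alpha mu2.
inline void tsce_roots(double alpha, double beta, double mu2, double &p,
                       double &q) {
  double g = alpha - beta - mu2;
  double sq = std::sqrt(g * g + 4.0 * alpha * mu2);
  p = (-g - sq) / 2.0;
  q = (g + sq > 0.0) ? (2.0 * alpha * mu2) / (g + sq) : (-g + sq) / 2.0;
}

// two-stage hazard h2(u), overflow-free (e^{-pu} factored out of the ratio)
inline double h2_eval(double u, double mu1, double alpha, double p, double q) {
  if (u <= 0.0) return 0.0;
  double E = std::exp((p - q) * u);  // in (0, 1]
  return (mu1 / alpha) * p * q * (E - 1.0) / (q - p * E);
}

inline double logS2_eval(double u, double mu1, double alpha, double p,
                         double q) {
  if (u <= 0.0) return 0.0;
  double E = std::exp((p - q) * u);
  return (mu1 / alpha) * (std::log(q - p) + p * u - std::log(q - p * E));
}

// cubic Hermite interpolation of the cumulative hazard; the derivative of
// Lambda is the rate itself, which is stored exactly at the grid points
inline double interp_lambda(const std::vector<double> &sg,
                            const std::vector<double> &Lg,
                            const std::vector<double> &Ng, double s) {
  if (s <= sg.front()) return Lg.front();
  if (s >= sg.back()) return Lg.back();
  size_t hi = std::upper_bound(sg.begin(), sg.end(), s) - sg.begin();
  size_t lo = hi - 1;
  double h = sg[hi] - sg[lo];
  double x = (s - sg[lo]) / h;
  double x2 = x * x, x3 = x2 * x;
  return (2 * x3 - 3 * x2 + 1) * Lg[lo] + (x3 - 2 * x2 + x) * h * Ng[lo] +
         (-2 * x3 + 3 * x2) * Lg[hi] + (x3 - x2) * h * Ng[hi];
}

}  // namespace

// [[Rcpp::export(rng = false)]]
NumericVector msce_hazard_kernel(NumericVector age, double B, double nu0,
                                 double mu1, double mu2, double alpha,
                                 double g, double lag, List trend,
                                 NumericVector gx, NumericVector gw,
                                 int ngrid) {
  TrendC tr;
  tr.w1 = as<double>(trend["w1"]);
  tr.w2 = as<double>(trend["w2"]);
  tr.y0 = as<double>(trend["y0"]);
  tr.s0 = as<double>(trend["s0"]);
  tr.b1 = as<double>(trend["b1"]);
  tr.b2 = as<double>(trend["b2"]);
  tr.atten = as<bool>(trend["log_attenuation"]);
  tr.cap = as<bool>(trend["cap_attenuation"]);

  double beta = alpha - g - mu2;
  if (!(beta > 0.0)) stop("derived cell death rate beta = alpha - g - mu2 is not positive");
  double p, q;
  tsce_roots(alpha, beta, mu2, p, q);
  if (!(q - p > 0.0)) stop("degenerate two-stage roots p == q");

  int n = age.size();
  NumericVector out(n);
  double tmax = 0.0;
  for (int i = 0; i < n; ++i) tmax = std::max(tmax, age[i] - lag);
  if (tmax <= 0.0) return out;

  // breakpoints of [0, tmax] at integrand kinks
  std::vector<double> bk;
  bk.push_back(0.0);
  if (tr.atten && tr.s0 > 0.0 && tr.s0 < tmax && B < tr.y0)
    bk.push_back(tr.s0);
  double yc = tr.y0 - B;
  if (B < tr.y0 && yc > 0.0 && yc < tmax) bk.push_back(yc);
  bk.push_back(tmax);
  std::sort(bk.begin(), bk.end());
  bk.erase(std::unique(bk.begin(), bk.end()), bk.end());
  // cap panel length so the fixed-order Gauss rule resolves the decaying
  // survival factor across wide integration ranges
  {
    const double max_len = 15.0;
    std::vector<double> bk2;
    for (size_t i = 0; i + 1 < bk.size(); ++i) {
      bk2.push_back(bk[i]);
      double len = bk[i + 1] - bk[i];
      int nsub = (int)std::ceil(len / max_len);
      for (int j = 1; j < nsub; ++j)
        bk2.push_back(bk[i] + len * j / nsub);
    }
    bk2.push_back(bk.back());
    bk = bk2;
  }

  // cumulative field-defect hazard Lambda(s) on a dense grid (Simpson)
  std::vector<double> sg, Lg, Ng;
  sg.push_back(0.0);
  Lg.push_back(0.0);
  Ng.push_back(nu_fd_eval(0.0, B, nu0, tr));
  double Lacc = 0.0;
  for (size_t seg = 0; seg + 1 < bk.size(); ++seg) {
    double a = bk[seg], b = bk[seg + 1];
    double len = b - a;
    int m = std::max(16, (int)std::lround((double)ngrid * len / tmax));
    if (m % 2) ++m;
    double h = len / m;
    std::vector<double> fv(m + 1);
    for (int k = 0; k <= m; ++k)
      fv[k] = nu_fd_eval(a + k * h, B, nu0, tr);
    for (int k = 0; k + 2 <= m; k += 2) {
      double L1 = Lacc + h / 12.0 * (5.0 * fv[k] + 8.0 * fv[k + 1] - fv[k + 2]);
      double L2 = Lacc + h / 3.0 * (fv[k] + 4.0 * fv[k + 1] + fv[k + 2]);
      sg.push_back(a + (k + 1) * h);
      Lg.push_back(L1);
      Ng.push_back(fv[k + 1]);
      sg.push_back(a + (k + 2) * h);
      Lg.push_back(L2);
      Ng.push_back(fv[k + 2]);
      Lacc = L2;
    }
  }

  int nq = gx.size();
  for (int i = 0; i < n; ++i) {
    double t = age[i] - lag;
    if (t <= 0.0) {
      out[i] = 0.0;
      continue;
    }
    double num = 0.0, denI = 0.0;
    for (size_t seg = 0; seg + 1 < bk.size(); ++seg) {
      double a = bk[seg];
      if (a >= t) break;
      double b = std::min(bk[seg + 1], t);
      double len = b - a;
      if (tr.atten && B < tr.y0 && b <= tr.s0) continue;  // nu == 0 there
      for (int j = 0; j < nq; ++j) {
        double s = a + len * gx[j];
        double w = len * gw[j];
        double fFD = nu_fd_eval(s, B, nu0, tr) *
                     std::exp(-interp_lambda(sg, Lg, Ng, s));
        if (fFD == 0.0) continue;
        double u = t - s;
        double S2 = std::exp(logS2_eval(u, mu1, alpha, p, q));
        num += w * fFD * h2_eval(u, mu1, alpha, p, q) * S2;
        denI += w * fFD * (1.0 - S2);
      }
    }
    double den = 1.0 - denI;
    if (!(den > 1e-12))
      stop("convolution denominator vanished: survival underflow at age %g",
           age[i]);
    out[i] = num / den;
  }
  return out;
}
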