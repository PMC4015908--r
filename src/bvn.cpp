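#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Standard normal CDF (double precision via erfc).
static inline double phid(double x) { return 0.5 * erfc(-x * M_SQRT1_2); }

// Genz's BVND algorithm (TVPACK): P(X > dh, Y > dk) for standard bivariate
// normal with correlation r.  Gauss-Legendre quadrature over a transformed
// integrand; a separate expansion handles |r| near 1.  Absolute accuracy
// is about 5e-16.
static double bvnd(double dh, double dk, double r) {
  static const double w1[] = {0.1713244923791704, 0.3607615730481386, 0.4679139345726910};
  static const double x1g[] = {0.9324695142031521, 0.6612093864662645, 0.2386191860831969};
  static const double w2[] = {0.04717533638651183, 0.1069393259953184, 0.1600783285433462,
                              0.2031674267230659, 0.2334925365383548, 0.2491470458134028};
  static const double x2g[] = {0.9815606342467192, 0.9041172563704749, 0.7699026741943047,
                               0.5873179542866175, 0.3678314989981802, 0.1252334085114689};
  static const double w3[] = {0.01761400713915212, 0.04060142980038694, 0.06267204833410907,
                              0.08327674157670475, 0.1019301198172404, 0.1181945319615184,
                              0.1316886384491766, 0.1420961093183820, 0.1491729864726037,
                              0.1527533871307258};
  static const double x3g[] = {0.9931285991850949, 0.9639719272779138, 0.9122344282513259,
                               0.8391169718222188, 0.7463319064601508, 0.6360536807265150,
                               0.5108670019508271, 0.3737060887154195, 0.2277858511416451,
                               0.07652652113349734};
  const double twopi = 6.283185307179586;
  const double *w, *x;
  int lg;
  if (std::fabs(r) < 0.3)      { lg = 3;  w = w1; x = x1g; }
  else if (std::fabs(r) < 0.75){ lg = 6;  w = w2; x = x2g; }
  else                         { lg = 10; w = w3; x = x3g; }
  double h = dh, k = dk, hk = h * k, bvn = 0.0;
  if (std::fabs(r) < 0.925) {
    if (std::fabs(r) > 0) {
      double hs = (h * h + k * k) / 2, asr = std::asin(r);
      for (int i = 0; i < lg; i++) {
        for (int is = -1; is <= 1; is += 2) {
          double sn = std::sin(asr * (is * x[i] + 1) / 2);
          bvn += w[i] * std::exp((sn * hk - hs) / (1 - sn * sn));
        }
      }
      bvn = bvn * asr / (2 * twopi);
    }
    bvn += phid(-h) * phid(-k);
  } else {
    if (r < 0) { k = -k; hk = -hk; }
    if (std::fabs(r) < 1) {
      double as = (1 - r) * (1 + r), a = std::sqrt(as), bs = (h - k) * (h - k);
      double c = (4 - hk) / 8, d = (12 - hk) / 16, asr = -(bs / as + hk) / 2;
      if (asr > -100)
        bvn = a * std::exp(asr) * (1 - c * (bs - as) * (1 - d * bs / 5) / 3 + c * d * as * as / 5);
      if (-hk < 100) {
        double b = std::sqrt(bs), sp = std::sqrt(twopi) * phid(-b / a);
        bvn -= std::exp(-hk / 2) * sp * b * (1 - c * bs * (1 - d * bs / 5) / 3);
      }
      a = a / 2;
      for (int i = 0; i < lg; i++) {
        for (int is = -1; is <= 1; is += 2) {
          double xs = a * (is * x[i] + 1); xs = xs * xs;
          double rs = std::sqrt(1 - xs), asr2 = -(bs / xs + hk) / 2;
          if (asr2 > -100) {
            double sp = 1 + c * xs * (1 + d * xs);
            double ep = std::exp(-hk * (1 - rs) / (2 * (1 + rs))) / rs;
            bvn += a * w[i] * std::exp(asr2) * (ep - sp);
          }
        }
      }
      bvn = -bvn / twopi;
    }
    if (r > 0) bvn += phid(-std::max(h, k));
    else {
      bvn = -bvn;
      if (k > h) bvn += phid(k) - phid(h);
    }
  }
  return bvn;
}

// P(Z1 <= h, Z2 <= k) for standard bivariate normal, correlation rho.
static inline double bvn_cdf1(double h, double k, double rho) {
  if (ISNAN(h) || ISNAN(k)) return NA_REAL;
  if (h == R_NegInf || k == R_NegInf) return 0.0;
  if (h == R_PosInf) return phid(k);
  if (k == R_PosInf) return phid(h);
  if (rho >= 1)  return phid(std::min(h, k));
  if (rho <= -1) return std::max(0.0, phid(h) + phid(k) - 1.0);
  double p = bvnd(-h, -k, rho);
  if (p < 0) p = 0; if (p > 1) p = 1;
  return p;
}

// [[Rcpp::export]]
NumericVector bvn_cdf_cpp(NumericVector h, NumericVector k, NumericVector rho) {
  R_xlen_t n = std::max(h.size(), std::max(k.size(), rho.size()));
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; i++)
    out[i] = bvn_cdf1(h[i % h.size()], k[i % k.size()], rho[i % rho.size()]);
  return out;
}

// Probability of quadrant q (1..4, Table-style: 1 = both at/above, 2 = test 1
// at/above only, 3 = test 2 at/above only, 4 = both below) for N((m1,m2),
// diag(s1,s2) %*% R %*% diag(s1,s2)) with thresholds (a1, a2).
static double quad_prob(double m1, double m2, double s1, double s2, double rho,
                        double a1, double a2, int q) {
  double h1 = (a1 - m1) / s1, h2 = (a2 - m2) / s2;
  double p11 = bvn_cdf1(h1, h2, rho);           // both below
  double p1 = phid(h1), p2 = phid(h2);
  switch (q) {
    case 1: return 1 - p1 - p2 + p11;
    case 2: return p2 - p11;
    case 3: return p1 - p11;
    default: return p11;
  }
}

// [[Rcpp::export]]
double quad_prob_cpp(double m1, double m2, double s1, double s2, double rho,
                     double a1, double a2, int q) {
  return quad_prob(m1, m2, s1, s2, rho, a1, a2, q);
}

// Negative log-likelihood of a bivariate Gaussian truncated to quadrant q.
// par = (mu1, mu2, log sd1, log sd2, atanh rho); x1, x2 lie inside the quadrant.
// [[Rcpp::export]]
double tbvn_negloglik_cpp(NumericVector par, NumericVector x1, NumericVector x2,
                          double a1, double a2, int q) {
  double m1 = par[0], m2 = par[1];
  double s1 = std::exp(par[2]), s2 = std::exp(par[3]), rho = std::tanh(par[4]);
  if (!R_FINITE(m1) || !R_FINITE(m2) || !R_FINITE(s1) || !R_FINITE(s2)) return 1e12;
  double p = quad_prob(m1, m2, s1, s2, rho, a1, a2, q);
  if (!R_FINITE(p) || p < 1e-300) return 1e12;
  double omr2 = 1 - rho * rho;
  if (omr2 < 1e-12) return 1e12;
  R_xlen_t n = x1.size();
  double cst = -std::log(2 * M_PI) - std::log(s1) - std::log(s2) - 0.5 * std::log(omr2);
  double ll = 0.0;
  for (R_xlen_t i = 0; i < n; i++) {
    double z1 = (x1[i] - m1) / s1, z2 = (x2[i] - m2) / s2;
    ll += cst - (z1 * z1 - 2 * rho * z1 * z2 + z2 * z2) / (2 * omr2);
  }
  ll -= n * std::log(p);
  if (!R_FINITE(ll)) return 1e12;
  return -ll;
}
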