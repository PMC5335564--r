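// Characteristic function of the transverse-isotropic free plate,
// partial-wave construction (see R/characteristic.R for the derivation and
// the normalization conventions). Hot path of mode tracing and inversion.

#include <Rcpp.h>
#include <complex>
#include <cmath>

using std::complex;

namespace {

// cos(q L) and sin(q L)/q for X = q^2, real arithmetic
inline void trig_real(double X, double L, double &c, double &s) {
  if (X > 1e-24) {
    double q = std::sqrt(X);
    c = std::cos(q * L);
    s = std::sin(q * L) / q;
  } else if (X < -1e-24) {
    double q = std::sqrt(-X);
    c = std::cosh(q * L);
    s = std::sinh(q * L) / q;
  } else {
    c = 1.0;
    s = L;
  }
}

inline void trig_cplx(const complex<double> &X, double L,
                      complex<double> &c, complex<double> &s) {
  complex<double> q = std::sqrt(X);
  c = std::cos(q * L);
  if (std::abs(X) <= 1e-24) {
    s = L;
  } else {
    s = std::sin(q * L) / q;
  }
}

}  // namespace

// [[Rcpp::export(name = ".plate_char_cpp")]]
Rcpp::NumericVector plate_char_cpp(double al, double be, double de, double ga,
                                   double hh, Rcpp::NumericVector f,
                                   Rcpp::NumericVector k, bool sym) {
  const R_xlen_t n = f.size();
  Rcpp::NumericVector out(n);
  const double A2 = al * ga;
  for (R_xlen_t i = 0; i < n; ++i) {
    const double w2 = 4.0 * M_PI * M_PI * f[i] * f[i];
    const double kk = k[i];
    const double k2 = kk * kk;
    const double A1 = al * (be * k2 - w2) + ga * (ga * k2 - w2) -
                      (de + ga) * (de + ga) * k2;
    const double A0 = (ga * k2 - w2) * (be * k2 - w2);
    const double disc = A1 * A1 - 4.0 * A2 * A0;
    const double ahat = (de + ga) * kk;
    double g = 1.0;
    if (sym) {
      g = ga * k2 - w2;
      if (std::fabs(g) < 1e-30) g = 1e-30;
    }
    if (disc >= 0.0) {
      const double sq = std::sqrt(disc);
      const double X1 = (-A1 + sq) / (2.0 * A2);
      const double X2 = (-A1 - sq) / (2.0 * A2);
      const double wa1 = al * X1 + ga * k2 - w2;
      const double wa2 = al * X2 + ga * k2 - w2;
      const double F1 = al * ahat * X1 - de * kk * wa1;
      const double F2 = al * ahat * X2 - de * kk * wa2;
      const double G1 = kk * ahat - wa1;
      const double G2 = kk * ahat - wa2;
      double c1, s1, c2, s2;
      trig_real(X1, hh, c1, s1);
      trig_real(X2, hh, c2, s2);
      double P1, P2, Q1, Q2;
      if (sym) {
        P1 = F1 * c1; P2 = F2 * c2;
        Q1 = G1 * s1 * X1; Q2 = G2 * s2 * X2;
      } else {
        P1 = F1 * s1; P2 = F2 * s2;
        Q1 = G1 * c1; Q2 = G2 * c2;
      }
      double dX = X1 - X2;
      if (std::fabs(dX) < 1e-300) dX = 1e-300;
      const double num = (P1 * Q2 - P2 * Q1) / (dX * g);
      const double den = (std::fabs(P1 * Q2) + std::fabs(P2 * Q1)) /
                             (std::fabs(dX) * std::fabs(g)) + 1e-300;
      out[i] = num / den;
    } else {
      const complex<double> sq = std::sqrt(complex<double>(disc, 0.0));
      const complex<double> X1 = (-A1 + sq) / (2.0 * A2);
      const complex<double> X2 = (-A1 - sq) / (2.0 * A2);
      const complex<double> wa1 = al * X1 + (ga * k2 - w2);
      const complex<double> wa2 = al * X2 + (ga * k2 - w2);
      const complex<double> F1 = al * ahat * X1 - de * kk * wa1;
      const complex<double> F2 = al * ahat * X2 - de * kk * wa2;
      const complex<double> G1 = kk * ahat - wa1;
      const complex<double> G2 = kk * ahat - wa2;
      complex<double> c1, s1, c2, s2;
      trig_cplx(X1, hh, c1, s1);
      trig_cplx(X2, hh, c2, s2);
      complex<double> P1, P2, Q1, Q2;
      if (sym) {
        P1 = F1 * c1; P2 = F2 * c2;
        Q1 = G1 * s1 * X1; Q2 = G2 * s2 * X2;
      } else {
        P1 = F1 * s1; P2 = F2 * s2;
        Q1 = G1 * c1; Q2 = G2 * c2;
      }
      const complex<double> dX = X1 - X2;
      const double num = std::real((P1 * Q2 - P2 * Q1) / (dX * g));
      const double den = (std::abs(P1 * Q2) + std::abs(P2 * Q1)) /
                             (std::abs(dX) * std::fabs(g)) + 1e-300;
      out[i] = num / den;
    }
  }
  return out;
}
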