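// Continuous-time local-linear-trend (integrated random walk) Kalman
// filter and RTS smoother for irregularly sampled 1-D position series.
// State: (position, velocity); F(dt) = [[1, dt], [0, 1]];
// Q(dt) = q * [[dt^3/3, dt^2/2], [dt^2/2, dt]]; observation z = pos + N(0, r).
#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
double kalman_llt_loglik(NumericVector t, NumericVector z, double q, double r) {
  int n = z.size();
  double x0 = z[0], x1 = 0.0;                 // state mean
  double p00 = r + 1e6, p01 = 0.0, p11 = 100.0; // diffuse-ish init
  double ll = 0.0;
  for (int k = 1; k < n; ++k) {
    double dt = t[k] - t[k - 1];
    // predict
    double a0 = x0 + dt * x1, a1 = x1;
    double q00 = q * dt * dt * dt / 3.0, q01 = q * dt * dt / 2.0, q11 = q * dt;
    double pp00 = p00 + 2.0 * dt * p01 + dt * dt * p11 + q00;
    double pp01 = p01 + dt * p11 + q01;
    double pp11 = p11 + q11;
    // update
    double s = pp00 + r;
    double v = z[k] - a0;
    ll += -0.5 * (std::log(2.0 * M_PI * s) + v * v / s);
    double k0 = pp00 / s, k1 = pp01 / s;
    x0 = a0 + k0 * v; x1 = a1 + k1 * v;
    p00 = (1.0 - k0) * pp00;
    p01 = (1.0 - k0) * pp01;
    p11 = pp11 - k1 * pp01;
  }
  return ll;
}

// [[Rcpp::export]]
NumericVector kalman_llt_smooth(NumericVector t, NumericVector z,
                                double q, double r) {
  int n = z.size();
  NumericVector fx0(n), fx1(n), fp00(n), fp01(n), fp11(n); // filtered
  NumericVector ax0(n), ax1(n), ap00(n), ap01(n), ap11(n); // predicted
  double x0 = z[0], x1 = 0.0;
  double p00 = r + 1e6, p01 = 0.0, p11 = 100.0;
  fx0[0] = x0; fx1[0] = x1; fp00[0] = p00; fp01[0] = p01; fp11[0] = p11;
  ax0[0] = x0; ax1[0] = x1; ap00[0] = p00; ap01[0] = p01; ap11[0] = p11;
  for (int k = 1; k < n; ++k) {
    double dt = t[k] - t[k - 1];
    double a0 = x0 + dt * x1, a1 = x1;
    double q00 = q * dt * dt * dt / 3.0, q01 = q * dt * dt / 2.0, q11 = q * dt;
    double pp00 = p00 + 2.0 * dt * p01 + dt * dt * p11 + q00;
    double pp01 = p01 + dt * p11 + q01;
    double pp11 = p11 + q11;
    ax0[k] = a0; ax1[k] = a1; ap00[k] = pp00; ap01[k] = pp01; ap11[k] = pp11;
    double s = pp00 + r, v = z[k] - a0;
    double k0 = pp00 / s, k1 = pp01 / s;
    x0 = a0 + k0 * v; x1 = a1 + k1 * v;
    p00 = (1.0 - k0) * pp00;
    p01 = (1.0 - k0) * pp01;
    p11 = pp11 - k1 * pp01;
    fx0[k] = x0; fx1[k] = x1; fp00[k] = p00; fp01[k] = p01; fp11[k] = p11;
  }
  // RTS backward pass
  NumericVector s0(n), s1(n);
  double sx0 = fx0[n - 1], sx1 = fx1[n - 1];
  double sp00 = fp00[n - 1], sp01 = fp01[n - 1], sp11 = fp11[n - 1];
  s0[n - 1] = sx0; s1[n - 1] = sx1;
  for (int k = n - 2; k >= 0; --k) {
    double dt = t[k + 1] - t[k];
    // C = P_f F' P_pred^{-1}; 2x2 inverse of predicted covariance at k+1
    double pp00 = ap00[k + 1], pp01 = ap01[k + 1], pp11 = ap11[k + 1];
    double det = pp00 * pp11 - pp01 * pp01;
    if (det < 1e-12) det = 1e-12;
    double i00 = pp11 / det, i01 = -pp01 / det, i11 = pp00 / det;
    // P_f F' = [[p00 + dt p01, p01], [p01 + dt p11, p11]]
    double b00 = fp00[k] + dt * fp01[k], b01 = fp01[k];
    double b10 = fp01[k] + dt * fp11[k], b11 = fp11[k];
    double c00 = b00 * i00 + b01 * i01, c01 = b00 * i01 + b01 * i11;
    double c10 = b10 * i00 + b11 * i01, c11 = b10 * i01 + b11 * i11;
    double d0 = sx0 - ax0[k + 1], d1 = sx1 - ax1[k + 1];
    double nx0 = fx0[k] + c00 * d0 + c01 * d1;
    double nx1 = fx1[k] + c10 * d0 + c11 * d1;
    // smoothed covariance P_s = P_f + C (P_s(k+1) - P_pred) C'
    double e00 = sp00 - pp00, e01 = sp01 - pp01, e11 = sp11 - pp11;
    double t00 = c00 * e00 + c01 * e01, t01 = c00 * e01 + c01 * e11;
    double t10 = c10 * e00 + c11 * e01, t11 = c10 * e01 + c11 * e11;
    sp00 = fp00[k] + t00 * c00 + t01 * c01;
    sp01 = fp01[k] + t00 * c10 + t01 * c11;
    sp11 = fp11[k] + t10 * c10 + t11 * c11;
    sx0 = nx0; sx1 = nx1;
    s0[k] = sx0; s1[k] = sx1;
  }
  return s0;
}
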