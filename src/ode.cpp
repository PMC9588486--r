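// Adaptive Cash-Karp Runge-Kutta integration of the full and Rational ERK
// vector fields.  Used on hot paths (region sampling, likelihood-ratio
// calibration) where the per-call overhead of a general-purpose solver
// dominates; agreement with the deSolve route is asserted in the tests.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

typedef void (*RhsFn)(const double*, const double*, double*);

// state: S0, C1, C2, S1, S2, E ; params: kf1, kr1, kc1, kf2, kr2, kc2
static void full_rhs_c(const double* x, const double* p, double* dx) {
  double bind1 = p[0] * x[5] * x[0];
  double bind2 = p[3] * x[5] * x[3];
  dx[0] = -bind1 + p[1] * x[1];
  dx[1] = bind1 - (p[1] + p[2]) * x[1];
  dx[2] = p[2] * x[1] - (p[4] + p[5]) * x[2] + bind2;
  dx[3] = -bind2 + p[4] * x[2];
  dx[4] = p[5] * x[2];
  dx[5] = -bind1 + p[1] * x[1] - bind2 + (p[4] + p[5]) * x[2];
}

// state: S0, S1, S2 ; params: kappa1, kappa2, pi, gamma1, gamma2
static void rational_rhs_c(const double* x, const double* p, double* dx) {
  double den = p[3] * x[0] + p[4] * x[1] + 1.0;
  double k1S0 = p[0] * x[0], k2S1 = p[1] * x[1];
  dx[0] = -k1S0 / den;
  dx[1] = (-k2S1 + (1.0 - p[2]) * k1S0) / den;
  dx[2] = (p[2] * k1S0 + k2S1) / den;
}

static const double B21 = 0.2,
  B31 = 3.0 / 40.0, B32 = 9.0 / 40.0,
  B41 = 0.3, B42 = -0.9, B43 = 1.2,
  B51 = -11.0 / 54.0, B52 = 2.5, B53 = -70.0 / 27.0, B54 = 35.0 / 27.0,
  B61 = 1631.0 / 55296.0, B62 = 175.0 / 512.0, B63 = 575.0 / 13824.0,
  B64 = 44275.0 / 110592.0, B65 = 253.0 / 4096.0,
  C1 = 37.0 / 378.0, C3 = 250.0 / 621.0, C4 = 125.0 / 594.0,
  C6 = 512.0 / 1771.0,
  D1 = C1 - 2825.0 / 27648.0, D3 = C3 - 18575.0 / 48384.0,
  D4 = C4 - 13525.0 / 55296.0, D5 = -277.0 / 14336.0, D6 = C6 - 0.25;

static NumericMatrix integrate_ck(RhsFn rhs, int n, const double* p,
                                  std::vector<double> x,
                                  const NumericVector& times,
                                  double rtol, double atol,
                                  long maxsteps, bool* overflow) {
  int nt = times.size();
  long steps = 0;
  NumericMatrix out(n, nt);
  std::vector<double> k1(n), k2(n), k3(n), k4(n), k5(n), k6(n),
    xt(n), xerr(n), xnew(n);
  double t = 0.0, h = times[0] > 0 ? times[0] / 10.0 : 1e-3;
  for (int m = 0; m < nt; ++m) {
    double tend = times[m];
    while (t < tend) {
      if (t + h > tend) h = tend - t;
      rhs(x.data(), p, k1.data());
      for (int i = 0; i < n; ++i) xt[i] = x[i] + h * B21 * k1[i];
      rhs(xt.data(), p, k2.data());
      for (int i = 0; i < n; ++i)
        xt[i] = x[i] + h * (B31 * k1[i] + B32 * k2[i]);
      rhs(xt.data(), p, k3.data());
      for (int i = 0; i < n; ++i)
        xt[i] = x[i] + h * (B41 * k1[i] + B42 * k2[i] + B43 * k3[i]);
      rhs(xt.data(), p, k4.data());
      for (int i = 0; i < n; ++i)
        xt[i] = x[i] + h * (B51 * k1[i] + B52 * k2[i] + B53 * k3[i] +
                            B54 * k4[i]);
      rhs(xt.data(), p, k5.data());
      for (int i = 0; i < n; ++i)
        xt[i] = x[i] + h * (B61 * k1[i] + B62 * k2[i] + B63 * k3[i] +
                            B64 * k4[i] + B65 * k5[i]);
      rhs(xt.data(), p, k6.data());
      double errmax = 0.0;
      for (int i = 0; i < n; ++i) {
        xnew[i] = x[i] + h * (C1 * k1[i] + C3 * k3[i] + C4 * k4[i] +
                              C6 * k6[i]);
        xerr[i] = h * (D1 * k1[i] + D3 * k3[i] + D4 * k4[i] +
                       D5 * k5[i] + D6 * k6[i]);
        double sc = atol + rtol * std::max(std::fabs(x[i]),
                                           std::fabs(xnew[i]));
        errmax = std::max(errmax, std::fabs(xerr[i]) / sc);
      }
      if (errmax <= 1.0) {
        t += h;
        x = xnew;
        h *= std::min(5.0, 0.9 * std::pow(std::max(errmax, 1e-16), -0.2));
      } else {
        h *= std::max(0.1, 0.9 * std::pow(errmax, -0.25));
      }
      if (h < 1e-14)
        stop("integration failure (step underflow) at t = %f", t);
      if (++steps > maxsteps) { *overflow = true; return out; }
    }
    for (int i = 0; i < n; ++i) out(i, m) = x[i];
  }
  *overflow = false;
  return out;
}

// Analytic Jacobian of the Rational model right-hand side.
static void rational_jac(const double* x, const double* p, double J[3][3]) {
  double den = p[3] * x[0] + p[4] * x[1] + 1.0;
  double den2 = den * den;
  double N0 = -p[0] * x[0];
  double N1 = -p[1] * x[1] + (1.0 - p[2]) * p[0] * x[0];
  double N2 = p[2] * p[0] * x[0] + p[1] * x[1];
  J[0][0] = (-p[0] * den - N0 * p[3]) / den2;
  J[0][1] = -N0 * p[4] / den2;
  J[0][2] = 0.0;
  J[1][0] = ((1.0 - p[2]) * p[0] * den - N1 * p[3]) / den2;
  J[1][1] = (-p[1] * den - N1 * p[4]) / den2;
  J[1][2] = 0.0;
  J[2][0] = (p[2] * p[0] * den - N2 * p[3]) / den2;
  J[2][1] = (p[1] * den - N2 * p[4]) / den2;
  J[2][2] = 0.0;
}

// Solve A x = b for a 3x3 system (partial pivoting), in place.
static void solve3(double A[3][3], double* b) {
  int piv[3] = {0, 1, 2};
  for (int c = 0; c < 2; ++c) {
    int best = c;
    for (int r = c + 1; r < 3; ++r)
      if (std::fabs(A[piv[r]][c]) > std::fabs(A[piv[best]][c])) best = r;
    std::swap(piv[c], piv[best]);
    for (int r = c + 1; r < 3; ++r) {
      double f = A[piv[r]][c] / A[piv[c]][c];
      A[piv[r]][c] = f;
      for (int cc = c + 1; cc < 3; ++cc) A[piv[r]][cc] -= f * A[piv[c]][cc];
    }
  }
  double y[3];
  y[0] = b[piv[0]];
  y[1] = b[piv[1]] - A[piv[1]][0] * y[0];
  y[2] = b[piv[2]] - A[piv[2]][0] * y[0] - A[piv[2]][1] * y[1];
  double xs[3];
  xs[2] = y[2] / A[piv[2]][2];
  xs[1] = (y[1] - A[piv[1]][2] * xs[2]) / A[piv[1]][1];
  xs[0] = (y[0] - A[piv[0]][1] * xs[1] - A[piv[0]][2] * xs[2]) /
    A[piv[0]][0];
  b[0] = xs[0]; b[1] = xs[1]; b[2] = xs[2];
}

// L-stable Rosenbrock pair (ode23s scheme) for the Rational model; used
// when the explicit method is stability-limited (large rate parameters).
static NumericMatrix integrate_ros23_rational(const double* p,
                                              std::vector<double> x,
                                              const NumericVector& times,
                                              double rtol, double atol) {
  const double d = 1.0 / (2.0 + std::sqrt(2.0));
  const double e32 = 6.0 + std::sqrt(2.0);
  int nt = times.size();
  NumericMatrix out(3, nt);
  double t = 0.0, h = 1e-4;
  double f0[3], f1[3], f2[3], k1[3], k2[3], k3[3], yt[3], yn[3], J[3][3];
  for (int m = 0; m < nt; ++m) {
    double tend = times[m];
    while (t < tend) {
      if (t + h > tend) h = tend - t;
      rational_rhs_c(x.data(), p, f0);
      rational_jac(x.data(), p, J);
      double W[3][3];
      for (int i = 0; i < 3; ++i)
        for (int j = 0; j < 3; ++j)
          W[i][j] = (i == j ? 1.0 : 0.0) - h * d * J[i][j];
      double Wk[3][3], rhsv[3];
      // k1
      std::copy(&W[0][0], &W[0][0] + 9, &Wk[0][0]);
      for (int i = 0; i < 3; ++i) rhsv[i] = f0[i];
      solve3(Wk, rhsv);
      for (int i = 0; i < 3; ++i) k1[i] = rhsv[i];
      for (int i = 0; i < 3; ++i) yt[i] = x[i] + 0.5 * h * k1[i];
      rational_rhs_c(yt, p, f1);
      // k2
      std::copy(&W[0][0], &W[0][0] + 9, &Wk[0][0]);
      for (int i = 0; i < 3; ++i) rhsv[i] = f1[i] - k1[i];
      solve3(Wk, rhsv);
      for (int i = 0; i < 3; ++i) k2[i] = rhsv[i] + k1[i];
      for (int i = 0; i < 3; ++i) yn[i] = x[i] + h * k2[i];
      rational_rhs_c(yn, p, f2);
      // k3 and embedded error estimate
      std::copy(&W[0][0], &W[0][0] + 9, &Wk[0][0]);
      for (int i = 0; i < 3; ++i)
        rhsv[i] = f2[i] - e32 * (k2[i] - f1[i]) - 2.0 * (k1[i] - f0[i]);
      solve3(Wk, rhsv);
      for (int i = 0; i < 3; ++i) k3[i] = rhsv[i];
      double errmax = 0.0;
      for (int i = 0; i < 3; ++i) {
        double err = h / 6.0 * (k1[i] - 2.0 * k2[i] + k3[i]);
        double sc = atol + rtol * std::max(std::fabs(x[i]),
                                           std::fabs(yn[i]));
        errmax = std::max(errmax, std::fabs(err) / sc);
      }
      if (errmax <= 1.0) {
        t += h;
        for (int i = 0; i < 3; ++i) x[i] = yn[i];
        h *= std::min(5.0, 0.9 * std::pow(std::max(errmax, 1e-16),
                                          -1.0 / 3.0));
      } else {
        h *= std::max(0.1, 0.9 * std::pow(errmax, -1.0 / 3.0));
      }
      if (h < 1e-14)
        stop("integration failure (step underflow) at t = %f", t);
    }
    for (int i = 0; i < 3; ++i) out(i, m) = x[i];
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix ode_full_cpp(NumericVector params, double S_tot, double E_tot,
                           NumericVector times, double rtol, double atol) {
  std::vector<double> x0 = {S_tot, 0.0, 0.0, 0.0, 0.0, E_tot};
  bool overflow = false;
  NumericMatrix out = integrate_ck(full_rhs_c, 6, params.begin(), x0,
                                   times, rtol, atol, 100000000L,
                                   &overflow);
  if (overflow) stop("integration failure (step budget exhausted)");
  return out;
}

// [[Rcpp::export]]
NumericMatrix ode_rational_cpp(NumericVector params, double S_tot,
                               NumericVector times, double rtol,
                               double atol) {
  std::vector<double> x0 = {S_tot, 0.0, 0.0};
  bool overflow = false;
  NumericMatrix out = integrate_ck(rational_rhs_c, 3, params.begin(), x0,
                                   times, rtol, atol, 2000L, &overflow);
  if (!overflow) return out;
  return integrate_ros23_rational(params.begin(), x0, times, rtol, atol);
}
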