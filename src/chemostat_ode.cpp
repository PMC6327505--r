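#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Right-hand side of the n-strain Monod chemostat:
//   dS/dt  = D (S_in - S) - sum_i mu_i(S) x_i / Y_i
//   dx_i/dt = (mu_i(S) - D) x_i,   mu_i(S) = mu_max_i S / (K_i + S)
static inline void chem_rhs(const double* y, int n,
                            const double* mu_max, const double* km,
                            const double* yld, double D, double S_in,
                            double* dy) {
  const double S = y[0];
  double cons = 0.0;
  for (int i = 0; i < n; ++i) {
    const double mu = mu_max[i] * S / (km[i] + S);
    dy[1 + i] = (mu - D) * y[1 + i];
    cons += mu * y[1 + i] / yld[i];
  }
  dy[0] = D * (S_in - S) - cons;
}

// Dormand-Prince 5(4) coefficients
static const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5, c5 = 8.0 / 9;
static const double a21 = 1.0 / 5;
static const double a31 = 3.0 / 40, a32 = 9.0 / 40;
static const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
static const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
                    a53 = 64448.0 / 6561, a54 = -212.0 / 729;
static const double a61 = 9017.0 / 3168, a62 = -355.0 / 33,
                    a63 = 46732.0 / 5247, a64 = 49.0 / 176,
                    a65 = -5103.0 / 18656;
static const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
                    b5 = -2187.0 / 6784, b6 = 11.0 / 84;
// embedded 4th-order weights
static const double e1 = 5179.0 / 57600, e3 = 7571.0 / 16695,
                    e4 = 393.0 / 640, e5 = -92097.0 / 339200,
                    e6 = 187.0 / 2100, e7 = 1.0 / 40;

//' @noRd
// [[Rcpp::export(name = ".chemostat_rk45", rng = false)]]
NumericMatrix chemostat_rk45(NumericVector times, NumericVector y0,
                             NumericVector mu_max, NumericVector km,
                             NumericVector yield_, double D, double S_in,
                             double rtol, double atol) {
  const int n = mu_max.size();
  const int m = 1 + n;
  const int nt = times.size();
  if (y0.size() != m) stop("state length must be 1 + number of strains");

  NumericMatrix out(nt, m);
  std::vector<double> y(y0.begin(), y0.end());
  std::vector<double> ytmp(m), ynew(m), err(m);
  std::vector<double> k1(m), k2(m), k3(m), k4(m), k5(m), k6(m), k7(m);
  const double* mm = &mu_max[0];
  const double* kk = &km[0];
  const double* yy = &yield_[0];

  for (int j = 0; j < m; ++j) out(0, j) = y[j];

  double t = times[0];
  double h = (times[nt - 1] - times[0]) / 100.0;
  if (h <= 0) stop("output times must be increasing");
  long nsteps = 0;
  const long max_steps = 5000000L;

  for (int kidx = 1; kidx < nt; ++kidx) {
    const double tend = times[kidx];
    if (!(tend > t)) stop("output times must be strictly increasing");
    while (t < tend) {
      if (h > tend - t) h = tend - t;
      if (++nsteps > max_steps)
        stop("integrator exceeded %ld steps at t = %g (h = %g)", max_steps, t, h);

      chem_rhs(y.data(), n, mm, kk, yy, D, S_in, k1.data());
      for (int j = 0; j < m; ++j) ytmp[j] = y[j] + h * a21 * k1[j];
      chem_rhs(ytmp.data(), n, mm, kk, yy, D, S_in, k2.data());
      for (int j = 0; j < m; ++j)
        ytmp[j] = y[j] + h * (a31 * k1[j] + a32 * k2[j]);
      chem_rhs(ytmp.data(), n, mm, kk, yy, D, S_in, k3.data());
      for (int j = 0; j < m; ++j)
        ytmp[j] = y[j] + h * (a41 * k1[j] + a42 * k2[j] + a43 * k3[j]);
      chem_rhs(ytmp.data(), n, mm, kk, yy, D, S_in, k4.data());
      for (int j = 0; j < m; ++j)
        ytmp[j] = y[j] + h * (a51 * k1[j] + a52 * k2[j] + a53 * k3[j] +
                              a54 * k4[j]);
      chem_rhs(ytmp.data(), n, mm, kk, yy, D, S_in, k5.data());
      for (int j = 0; j < m; ++j)
        ytmp[j] = y[j] + h * (a61 * k1[j] + a62 * k2[j] + a63 * k3[j] +
                              a64 * k4[j] + a65 * k5[j]);
      chem_rhs(ytmp.data(), n, mm, kk, yy, D, S_in, k6.data());
      for (int j = 0; j < m; ++j)
        ynew[j] = y[j] + h * (b1 * k1[j] + b3 * k3[j] + b4 * k4[j] +
                              b5 * k5[j] + b6 * k6[j]);
      chem_rhs(ynew.data(), n, mm, kk, yy, D, S_in, k7.data());
      for (int j = 0; j < m; ++j) {
        const double y4 = y[j] + h * (e1 * k1[j] + e3 * k3[j] + e4 * k4[j] +
                                      e5 * k5[j] + e6 * k6[j] + e7 * k7[j]);
        err[j] = ynew[j] - y4;
      }

      double errnorm = 0.0;
      for (int j = 0; j < m; ++j) {
        const double sc =
            atol + rtol * std::max(std::fabs(y[j]), std::fabs(ynew[j]));
        const double r = err[j] / sc;
        errnorm += r * r;
      }
      errnorm = std::sqrt(errnorm / m);

      if (errnorm <= 1.0) {
        t += h;
        for (int j = 0; j < m; ++j) {
          // concentrations and biomass cannot leave the non-negative orthant
          y[j] = (ynew[j] < 0.0) ? 0.0 : ynew[j];
        }
      }
      double fac = 0.9 * std::pow(std::max(errnorm, 1e-10), -0.2);
      if (fac < 0.2) fac = 0.2;
      if (fac > 5.0) fac = 5.0;
      h *= fac;
      if (h < 1e-13 * (std::fabs(t) + 1.0))
        stop("step size underflow at t = %g", t);
    }
    for (int j = 0; j < m; ++j) out(kidx, j) = y[j];
  }
  return out;
}
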