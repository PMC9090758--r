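#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Bilinear neural model + balloon-Windkessel hemodynamics, integrated with a
// fixed-step RK4 at micro-time resolution dt.  Inputs U (n_micro x 3) are
// held piecewise-constant within each micro step (so the coupling matrix is
// hoisted out of the RK4 stages): channel 1 is the (mean-centered) driving
// input, channels 2 and 3 the positive/negative valence modulators.  States
// per region: neural z plus (s, f, nu, q).  BOLD is sampled at mid-volume
// times (k - 0.5) * TR.

struct State {
  double z[4], s[4], f[4], nu[4], q[4];
};

struct Deriv {
  double z[4], s[4], f[4], nu[4], q[4];
};

// [[Rcpp::export]]
List cpp_dcm_simulate(const arma::mat &A, const arma::mat &Bp,
                      const arma::mat &Bn, const arma::mat &C,
                      const arma::mat &U, double dt, int n_vol, double TR,
                      double kappa, double gammah, const arma::vec &tau,
                      double alpha, double E0, double V0, double k1,
                      double k2, double k3, bool return_neural) {
  double At[4][4];
  for (int i = 0; i < 4; ++i)
    for (int j = 0; j < 4; ++j)
      At[i][j] = (i == j) ? -0.5 * std::exp(A(i, i)) : A(i, j);

  IntegerVector sample_idx(n_vol);
  int n_micro = 0;
  for (int k = 0; k < n_vol; ++k) {
    sample_idx[k] = (int)std::lround(((k + 0.5) * TR) / dt);
    if (sample_idx[k] + 1 > n_micro) n_micro = sample_idx[k] + 1;
  }
  if ((int)U.n_rows < n_micro)
    stop("input matrix has %d rows; %d micro steps required", U.n_rows, n_micro);

  const double ia = 1.0 / alpha;
  const double l1mE0 = std::log(1.0 - E0);
  const double itau[4] = {1.0 / tau[0], 1.0 / tau[1], 1.0 / tau[2],
                          1.0 / tau[3]};

  State x;
  for (int r = 0; r < 4; ++r) {
    x.z[r] = 0.0; x.s[r] = 0.0; x.f[r] = 1.0; x.nu[r] = 1.0; x.q[r] = 1.0;
  }

  arma::mat bold(4, n_vol, arma::fill::zeros);
  arma::mat neural;
  if (return_neural) neural.set_size(4, n_micro);
  bool ok = true;
  int next = 0;

  double J[4][4], Cu[4];
  Deriv kk[4];
  State y;

  for (int i = 0; i < n_micro; ++i) {
    if (return_neural)
      for (int r = 0; r < 4; ++r) neural(r, i) = x.z[r];
    while (next < n_vol && sample_idx[next] == i) {
      for (int r = 0; r < 4; ++r)
        bold(r, next) = V0 * (k1 * (1.0 - x.q[r]) +
                              k2 * (1.0 - x.q[r] / x.nu[r]) +
                              k3 * (1.0 - x.nu[r]));
      ++next;
    }
    const double u0 = U(i, 0), u1 = U(i, 1), u2 = U(i, 2);
    for (int r = 0; r < 4; ++r) {
      for (int c = 0; c < 4; ++c)
        J[r][c] = At[r][c] + u1 * Bp(r, c) + u2 * Bn(r, c);
      Cu[r] = C(r, 0) * u0 + C(r, 1) * u1 + C(r, 2) * u2;
    }

    const double w[4] = {0.0, 0.5, 0.5, 1.0};
    for (int stage = 0; stage < 4; ++stage) {
      if (stage == 0) {
        y = x;
      } else {
        const double h = w[stage] * dt;
        const Deriv &kp = kk[stage - 1];
        for (int r = 0; r < 4; ++r) {
          y.z[r] = x.z[r] + h * kp.z[r];
          y.s[r] = x.s[r] + h * kp.s[r];
          y.f[r] = x.f[r] + h * kp.f[r];
          y.nu[r] = x.nu[r] + h * kp.nu[r];
          y.q[r] = x.q[r] + h * kp.q[r];
          if (y.f[r] < 1e-6) y.f[r] = 1e-6;
          if (y.nu[r] < 1e-6) y.nu[r] = 1e-6;
          if (y.q[r] < 1e-6) y.q[r] = 1e-6;
        }
      }
      Deriv &kd = kk[stage];
      for (int r = 0; r < 4; ++r) {
        kd.z[r] = J[r][0] * y.z[0] + J[r][1] * y.z[1] + J[r][2] * y.z[2] +
                  J[r][3] * y.z[3] + Cu[r];
        kd.s[r] = y.z[r] - kappa * y.s[r] - gammah * (y.f[r] - 1.0);
        kd.f[r] = y.s[r];
        const double fout = std::pow(y.nu[r], ia);
        const double Ef = 1.0 - std::exp(l1mE0 / y.f[r]);
        kd.nu[r] = (y.f[r] - fout) * itau[r];
        kd.q[r] = (y.f[r] * Ef / E0 - fout * y.q[r] / y.nu[r]) * itau[r];
      }
    }
    const double d6 = dt / 6.0;
    double mx = 0.0;
    for (int r = 0; r < 4; ++r) {
      x.z[r] += d6 * (kk[0].z[r] + 2 * kk[1].z[r] + 2 * kk[2].z[r] + kk[3].z[r]);
      x.s[r] += d6 * (kk[0].s[r] + 2 * kk[1].s[r] + 2 * kk[2].s[r] + kk[3].s[r]);
      x.f[r] += d6 * (kk[0].f[r] + 2 * kk[1].f[r] + 2 * kk[2].f[r] + kk[3].f[r]);
      x.nu[r] += d6 * (kk[0].nu[r] + 2 * kk[1].nu[r] + 2 * kk[2].nu[r] + kk[3].nu[r]);
      x.q[r] += d6 * (kk[0].q[r] + 2 * kk[1].q[r] + 2 * kk[2].q[r] + kk[3].q[r]);
      if (x.f[r] < 1e-6) x.f[r] = 1e-6;
      if (x.nu[r] < 1e-6) x.nu[r] = 1e-6;
      if (x.q[r] < 1e-6) x.q[r] = 1e-6;
      double az = std::fabs(x.z[r]), aq = std::fabs(x.q[r]);
      if (az > mx) mx = az;
      if (aq > mx) mx = aq;
    }
    if (!std::isfinite(mx) || mx > 1e6) { ok = false; break; }
  }

  List out = List::create(Named("bold") = bold, Named("ok") = ok);
  if (return_neural) out["neural"] = neural;
  return out;
}
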