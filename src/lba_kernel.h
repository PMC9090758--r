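#ifndef ACCUMDCM_LBA_KERNEL_H
#define ACCUMDCM_LBA_KERNEL_H

#include <Rmath.h>
#include <cmath>

// Shared closed-form LBA first-passage kernel (positive-drift truncation).

namespace lba {

inline double phi_(double x) {
  if (x > 37.0 || x < -37.0) return 0.0;
  return 0.3989422804014327 * std::exp(-0.5 * x * x);
}
inline double Phi_(double x) {
  if (x > 8.0) return 1.0;       // |error| < 1e-15 at the cut
  if (x < -8.0) return 0.0;
  return 0.5 * std::erfc(-x * 0.7071067811865476);
}

inline double acc_cdf1(double t, double A, double b, double v, double sv) {
  if (t <= 0.0) return 0.0;
  double denom = Phi_(v / sv);
  if (denom < 1e-300) denom = 1e-300;
  double ts = t * sv;
  double F0;
  if (A < 1e-10 * b) {
    F0 = Phi_((t * v - b) / ts);
  } else {
    double z1 = (b - A - t * v) / ts;
    double z2 = (b - t * v) / ts;
    F0 = 1.0 + (b - A - t * v) / A * Phi_(z1) - (b - t * v) / A * Phi_(z2)
       + ts / A * (phi_(z1) - phi_(z2));
  }
  double F = F0 / denom;
  if (F < 0.0) F = 0.0;
  if (F > 1.0) F = 1.0;
  return F;
}

inline double acc_pdf1(double t, double A, double b, double v, double sv) {
  if (t <= 0.0) return 0.0;
  double denom = Phi_(v / sv);
  if (denom < 1e-300) denom = 1e-300;
  double ts = t * sv;
  double f0;
  if (A < 1e-10 * b) {
    double z2 = (b - t * v) / ts;
    f0 = b / (t * t * sv) * phi_(z2);
  } else {
    double z1 = (b - A - t * v) / ts;
    double z2 = (b - t * v) / ts;
    f0 = (-v * Phi_(z1) + sv * phi_(z1) + v * Phi_(z2) - sv * phi_(z2)) / A;
  }
  double f = f0 / denom;
  return f > 0.0 ? f : 0.0;
}

const double LOG_FLOOR = -1e10;

// variants with the positive-drift truncation mass precomputed
inline double acc_cdf1_d(double t, double A, double b, double v, double sv,
                         double denom) {
  if (t <= 0.0) return 0.0;
  double ts = t * sv;
  double F0;
  if (A < 1e-10 * b) {
    F0 = Phi_((t * v - b) / ts);
  } else {
    double z1 = (b - A - t * v) / ts;
    double z2 = (b - t * v) / ts;
    F0 = 1.0 + (b - A - t * v) / A * Phi_(z1) - (b - t * v) / A * Phi_(z2)
       + ts / A * (phi_(z1) - phi_(z2));
  }
  double F = F0 / denom;
  if (F < 0.0) F = 0.0;
  if (F > 1.0) F = 1.0;
  return F;
}

inline double acc_pdf1_d(double t, double A, double b, double v, double sv,
                         double denom) {
  if (t <= 0.0) return 0.0;
  double ts = t * sv;
  double f0;
  if (A < 1e-10 * b) {
    double z2 = (b - t * v) / ts;
    f0 = b / (t * t * sv) * phi_(z2);
  } else {
    double z1 = (b - A - t * v) / ts;
    double z2 = (b - t * v) / ts;
    f0 = (-v * Phi_(z1) + sv * phi_(z1) + v * Phi_(z2) - sv * phi_(z2)) / A;
  }
  double f = f0 / denom;
  return f > 0.0 ? f : 0.0;
}

inline double trunc_denom(double v, double sv) {
  double denom = Phi_(v / sv);
  return denom < 1e-300 ? 1e-300 : denom;
}

inline double trial_logdens_d(double rt, int cond, int correct, double A,
                              const double *b4, double t0, double sv,
                              const double *vt4, const double *vf4,
                              const double *den_t4, const double *den_f4) {
  double t = rt - t0;
  if (t <= 0.0) return LOG_FLOOR;
  double b = b4[cond];
  double vw, vl, svw, svl, dw, dl;
  if (correct) {
    vw = vt4[cond]; svw = sv;  dw = den_t4[cond];
    vl = vf4[cond]; svl = 1.0; dl = den_f4[cond];
  } else {
    vw = vf4[cond]; svw = 1.0; dw = den_f4[cond];
    vl = vt4[cond]; svl = sv;  dl = den_t4[cond];
  }
  double dens = acc_pdf1_d(t, A, b, vw, svw, dw) *
                (1.0 - acc_cdf1_d(t, A, b, vl, svl, dl));
  if (!(dens > 0.0) || !std::isfinite(dens)) return LOG_FLOOR;
  double ld = std::log(dens);
  return ld < LOG_FLOOR ? LOG_FLOOR : ld;
}

inline double trial_logdens(double rt, int cond, int correct, double A,
                            const double *b4, double t0, double sv,
                            const double *vt4, const double *vf4) {
  double den_t4[4], den_f4[4];
  for (int c = 0; c < 4; ++c) {
    den_t4[c] = trunc_denom(vt4[c], sv);
    den_f4[c] = trunc_denom(vf4[c], 1.0);
  }
  return trial_logdens_d(rt, cond, correct, A, b4, t0, sv, vt4, vf4,
                         den_t4, den_f4);
}

}  // namespace lba

#endif
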