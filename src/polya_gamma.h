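// Sampler for the Polya-Gamma distribution PG(1, z), used to augment the
// logistic Bernoulli nodes so that all conditional updates of loadings,
// difficulties and traits are Gaussian. Alternating-series accept/reject
// scheme with a truncated inverse-Gaussian body and exponential tail,
// split at t = 0.64. Draws use R's RNG (caller must hold an RNGScope).
#ifndef MMIRTREE_POLYA_GAMMA_H
#define MMIRTREE_POLYA_GAMMA_H

#include <Rmath.h>
#include <cmath>

namespace pg {

const double TRUNC = 0.64;

// n-th coefficient of the alternating series for the J*(1, .) density.
inline double a_coef(int n, double x) {
  double np5 = n + 0.5;
  if (x > TRUNC) {
    return M_PI * np5 * std::exp(-np5 * np5 * M_PI * M_PI * x / 2.0);
  }
  return M_PI * np5 * std::pow(2.0 / (M_PI * x), 1.5) *
         std::exp(-2.0 * np5 * np5 / x);
}

// CDF of the inverse-Gaussian(mu = 1/z, lambda = 1) at x; z = 0 gives the
// Levy limit. Evaluated in log space on the right tail to avoid overflow.
inline double pigauss(double x, double z) {
  double rx = 1.0 / std::sqrt(x);
  double b = rx * (x * z - 1.0);
  double a = -rx * (x * z + 1.0);
  return ::Rf_pnorm5(b, 0.0, 1.0, 1, 0) +
         std::exp(2.0 * z + ::Rf_pnorm5(a, 0.0, 1.0, 1, 1));
}

// Inverse-Gaussian(1/z, 1) truncated to (0, TRUNC).
inline double rtigauss(double z) {
  double x = TRUNC + 1.0;
  if (1.0 / z > TRUNC) {
    // small z: rejection from the truncated Levy via two exponentials
    for (;;) {
      double e1, e2;
      do {
        e1 = ::exp_rand();
        e2 = ::exp_rand();
      } while (e1 * e1 > 2.0 * e2 / TRUNC);
      x = TRUNC / ((1.0 + TRUNC * e1) * (1.0 + TRUNC * e1));
      if (::unif_rand() <= std::exp(-0.5 * z * z * x)) return x;
    }
  }
  double mu = 1.0 / z;
  while (x > TRUNC) {
    double y = ::norm_rand();
    y = y * y;
    double muy = mu * y;
    x = mu + 0.5 * mu * muy - 0.5 * mu * std::sqrt(4.0 * muy + muy * muy);
    if (::unif_rand() > mu / (mu + x)) x = mu * mu / x;
  }
  return x;
}

// One draw from PG(1, psi).
inline double rpg1(double psi) {
  double z = std::fabs(psi) * 0.5;
  double fz = M_PI * M_PI / 8.0 + z * z / 2.0;
  double p = (M_PI / (2.0 * fz)) * std::exp(-fz * TRUNC);
  double q = 2.0 * std::exp(-z) * pigauss(TRUNC, z);
  for (;;) {
    double x;
    if (::unif_rand() < p / (p + q)) {
      x = TRUNC + ::exp_rand() / fz;
    } else {
      x = rtigauss(z);
    }
    double s = a_coef(0, x);
    double y = ::unif_rand() * s;
    int n = 0;
    for (;;) {
      ++n;
      if (n % 2 == 1) {
        s -= a_coef(n, x);
        if (y <= s) return x / 4.0;
      } else {
        s += a_coef(n, x);
        if (y > s) break;
      }
    }
  }
}

}  // namespace pg

#endif
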