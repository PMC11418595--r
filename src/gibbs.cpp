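// Gibbs sampler for the mixture multidimensional IRTree model and its
// single-class benchmarks. All logistic Bernoulli nodes are augmented with
// Polya-Gamma latent variables, making the conditionals of loadings,
// difficulties and person traits Gaussian (loadings truncated to be
// positive). The proportionality constant omega has a conjugate normal
// conditional truncated to its uniform prior support. Trait correlations
// are updated by elementwise random-walk Metropolis under the elementwise
// U(-1,1) prior with rejection of non-positive-definite proposals. Class
// memberships are drawn from their categorical conditionals and the class
// proportions from a Dirichlet conditional.
//
// Randomness comes exclusively from R's RNG, so a set.seed() before the
// call makes a chain fully reproducible.

#include <Rcpp.h>
#include "polya_gamma.h"
#include <vector>
#include <cmath>

using namespace Rcpp;

static inline double softplus(double x) {
  if (x > 35.0) return x;
  if (x < -35.0) return 0.0;
  return std::log1p(std::exp(x));
}

// Bernoulli log-likelihood with logit link: y*psi - log(1 + e^psi).
static inline double bern_ll(int y, double psi) {
  return y * psi - softplus(psi);
}

// Normal(m, sd) truncated to (0, inf).
static double rtnorm_pos(double m, double sd) {
  double lower = -m / sd;
  if (lower < 0.0) {  // positive mean: plain rejection is fast
    for (int i = 0; i < 64; ++i) {
      double x = ::norm_rand();
      if (x > lower) return m + sd * x;
    }
  }
  // Robert (1995) exponential rejection, valid for any lower bound
  double alpha = 0.5 * (lower + std::sqrt(lower * lower + 4.0));
  for (;;) {
    double x = lower + ::exp_rand() / alpha;
    double rho = std::exp(-0.5 * (x - alpha) * (x - alpha));
    if (::unif_rand() <= rho) return m + sd * x;
  }
}

// Normal(m, sd) truncated to (lo, hi) via inverse CDF (bounds here are
// never far in the tails once the sampler has any data).
static double rtnorm_interval(double m, double sd, double lo, double hi) {
  double plo = ::Rf_pnorm5(lo, m, sd, 1, 0);
  double phi = ::Rf_pnorm5(hi, m, sd, 1, 0);
  if (phi - plo < 1e-14) return (m < lo) ? lo + 1e-8 : hi - 1e-8;
  double u = plo + ::unif_rand() * (phi - plo);
  double x = ::Rf_qnorm5(u, m, sd, 1, 0);
  if (x < lo) x = lo;
  if (x > hi) x = hi;
  return x;
}

// Cholesky of a d x d SPD matrix (row-major, d <= 3). Returns false if the
// matrix is not positive definite.
static bool chol3(const double* A, double* L, int d) {
  for (int i = 0; i < d * d; ++i) L[i] = 0.0;
  for (int i = 0; i < d; ++i) {
    for (int j = 0; j <= i; ++j) {
      double s = A[i * d + j];
      for (int k = 0; k < j; ++k) s -= L[i * d + k] * L[j * d + k];
      if (i == j) {
        if (s <= 1e-12) return false;
        L[i * d + i] = std::sqrt(s);
      } else {
        L[i * d + j] = s / L[j * d + j];
      }
    }
  }
  return true;
}

// Inverse of SPD matrix via its Cholesky factor.
static void inv_from_chol(const double* L, double* Ainv, int d) {
  // solve L Linv = I, then Ainv = Linv' Linv
  std::vector<double> Linv(d * d, 0.0);
  for (int c = 0; c < d; ++c) {
    Linv[c * d + c] = 1.0 / L[c * d + c];
    for (int i = c + 1; i < d; ++i) {
      double s = 0.0;
      for (int k = c; k < i; ++k) s -= L[i * d + k] * Linv[k * d + c];
      Linv[i * d + c] = s / L[i * d + i];
    }
  }
  for (int i = 0; i < d; ++i) {
    for (int j = 0; j < d; ++j) {
      double s = 0.0;
      for (int k = (i > j ? i : j); k < d; ++k) {
        s += Linv[k * d + i] * Linv[k * d + j];
      }
      Ainv[i * d + j] = s;
    }
  }
}

// Draw x ~ N(Q^{-1} b, Q^{-1}) for d x d precision Q (d <= 3).
static void mvn_precision_draw(const double* Q, const double* b, double* x,
                               int d) {
  double L[9];
  if (!chol3(Q, L, d)) stop("non-positive-definite precision in trait update");
  // mean: solve Q m = b via L L' m = b
  double u[3], m[3];
  for (int i = 0; i < d; ++i) {
    double s = b[i];
    for (int k = 0; k < i; ++k) s -= L[i * d + k] * u[k];
    u[i] = s / L[i * d + i];
  }
  for (int i = d - 1; i >= 0; --i) {
    double s = u[i];
    for (int k = i + 1; k < d; ++k) s -= L[k * d + i] * m[k];
    m[i] = s / L[i * d + i];
  }
  // noise: solve L' e = z
  double z[3], e[3];
  for (int i = 0; i < d; ++i) z[i] = ::norm_rand();
  for (int i = d - 1; i >= 0; --i) {
    double s = z[i];
    for (int k = i + 1; k < d; ++k) s -= L[k * d + i] * e[k];
    e[i] = s / L[i * d + i];
  }
  for (int i = 0; i < d; ++i) x[i] = m[i] + e[i];
}

struct Masks {
  static bool ers(int c) { return c == 0 || c == 2; }  // 0-based class
  static bool mrs(int c) { return c == 1 || c == 2; }
};

// [[Rcpp::export]]
List gibbs_irtree_chain(IntegerMatrix y, IntegerVector classes0,
                        bool mixture, IntegerVector z_init0,
                        NumericMatrix eta_init, List item_init,
                        NumericMatrix R_init, NumericVector pi_init,
                        LogicalVector trait_active, double loading_var,
                        double beta_var, double omega_lo, double omega_hi,
                        NumericVector dir_alpha, double cor_prop_sd,
                        int n_iter, int n_burn, int n_fix_z, bool store_z) {
  const int P = y.nrow(), J = y.ncol();
  const int nclass = classes0.size();
  RNGScope scope;

  // ---- pseudo-item data --------------------------------------------------
  std::vector<int> y0(P * J), y1(P * J), y2(P * J), obs1(P * J), obs2(P * J),
      sgn(P * J);
  for (int p = 0; p < P; ++p) {
    for (int j = 0; j < J; ++j) {
      int v = y(p, j);
      int idx = p * J + j;
      y0[idx] = (v <= 2) ? 1 : 0;
      obs1[idx] = (v >= 3) ? 1 : 0;
      y1[idx] = (v == 3) ? 1 : 0;
      obs2[idx] = (v != 3) ? 1 : 0;
      y2[idx] = (v == 1 || v == 5) ? 1 : 0;
      sgn[idx] = (v <= 2) ? -1 : 1;
    }
  }

  // ---- state -------------------------------------------------------------
  std::vector<double> ath = as<std::vector<double> >(item_init["ath"]);
  double omega = as<double>(item_init["omega"]);
  NumericMatrix aers_in = item_init["aers"], amrs_in = item_init["amrs"];
  NumericVector beta_in = item_init["beta"];  // J x 3 x 4, column-major
  std::vector<double> aers(J * 4), amrs(J * 4), beta(J * 3 * 4);
  for (int j = 0; j < J; ++j) {
    for (int c = 0; c < 4; ++c) {
      aers[j * 4 + c] = aers_in(j, c);
      amrs[j * 4 + c] = amrs_in(j, c);
      for (int k = 0; k < 3; ++k) {
        beta[(j * 3 + k) * 4 + c] = beta_in[j + J * k + J * 3 * c];
      }
    }
  }
  std::vector<double> eta(P * 3);
  for (int p = 0; p < P; ++p) {
    for (int t = 0; t < 3; ++t) eta[p * 3 + t] = eta_init(p, t);
  }
  std::vector<int> z(P);
  for (int p = 0; p < P; ++p) z[p] = z_init0[p];  // 0-based
  std::vector<double> pi(4);
  for (int c = 0; c < 4; ++c) pi[c] = pi_init[c];

  // active traits and the correlation matrix over them
  std::vector<int> act;
  for (int t = 0; t < 3; ++t) {
    if (trait_active[t]) act.push_back(t);
  }
  const int d = (int)act.size();
  double Rm[9], Rinv[9], Lchol[9];
  for (int i = 0; i < d; ++i) {
    for (int j2 = 0; j2 < d; ++j2) Rm[i * d + j2] = R_init(act[i], act[j2]);
  }
  if (!chol3(Rm, Lchol, d)) stop("initial trait correlation not PD");
  inv_from_chol(Lchol, Rinv, d);
  // free correlation pairs (i < j within active dims)
  std::vector<std::pair<int, int> > cor_pairs;
  for (int i = 0; i < d; ++i) {
    for (int j2 = i + 1; j2 < d; ++j2) cor_pairs.push_back(std::make_pair(i, j2));
  }

  // PG weights
  std::vector<double> w0(P * J), w1(P * J), w2(P * J);

  // linear predictors given current state
  auto psi0 = [&](int p, int j, int c) {
    return -ath[j] * eta[p * 3] - amrs[j * 4 + c] * eta[p * 3 + 2] -
           beta[(j * 3 + 0) * 4 + c];
  };
  auto psi1 = [&](int p, int j, int c) {
    return -ath[j] * eta[p * 3] + amrs[j * 4 + c] * eta[p * 3 + 2] -
           beta[(j * 3 + 1) * 4 + c];
  };
  auto psi2 = [&](int p, int j, int c) {
    return sgn[p * J + j] * omega * ath[j] * eta[p * 3] +
           aers[j * 4 + c] * eta[p * 3 + 1] - beta[(j * 3 + 2) * 4 + c];
  };
  auto cell_ll = [&](int p, int j, int c) {
    int idx = p * J + j;
    double ll = bern_ll(y0[idx], psi0(p, j, c));
    if (obs1[idx]) ll += bern_ll(y1[idx], psi1(p, j, c));
    if (obs2[idx]) ll += bern_ll(y2[idx], psi2(p, j, c));
    return ll;
  };

  // ---- output ------------------------------------------------------------
  // column layout (R side builds matching names):
  //   ath (J) | omega | aers free (J per class with ERS active) |
  //   amrs free | beta (J*3 per active class) | correlations (d*(d-1)/2) |
  //   pi (4, mixture only) | deviance
  int n_ers_cl = 0, n_mrs_cl = 0;
  for (int ci = 0; ci < nclass; ++ci) {
    if (Masks::ers(classes0[ci])) ++n_ers_cl;
    if (Masks::mrs(classes0[ci])) ++n_mrs_cl;
  }
  const int ncor = (int)cor_pairs.size();
  const int npar = J + 1 + J * n_ers_cl + J * n_mrs_cl + J * 3 * nclass +
                   ncor + (mixture ? 4 : 0) + 1;
  NumericMatrix draws(n_iter, npar);
  const int n_keep = n_iter - n_burn;
  IntegerMatrix z_draws((store_z && mixture) ? n_keep : 0, P);
  std::vector<double> eta_sum(P * 3, 0.0), eta_ss(P * 3, 0.0);
  std::vector<double> pz_count(P * 4, 0.0);
  int cor_accept = 0, cor_try = 0;

  std::vector<int> members_of(P);
  std::vector<std::vector<int> > members(4);

  for (int iter = 0; iter < n_iter; ++iter) {
    if (iter % 64 == 0) Rcpp::checkUserInterrupt();

    // membership lists for the item-parameter updates
    for (int c = 0; c < 4; ++c) members[c].clear();
    for (int p = 0; p < P; ++p) members[z[p]].push_back(p);

    // -- Polya-Gamma weights ----------------------------------------------
    for (int p = 0; p < P; ++p) {
      int c = z[p];
      for (int j = 0; j < J; ++j) {
        int idx = p * J + j;
        w0[idx] = pg::rpg1(psi0(p, j, c));
        if (obs1[idx]) w1[idx] = pg::rpg1(psi1(p, j, c));
        if (obs2[idx]) w2[idx] = pg::rpg1(psi2(p, j, c));
      }
    }

    // -- person traits -----------------------------------------------------
    for (int p = 0; p < P; ++p) {
      int c = z[p];
      double Q[9], b[3];
      for (int i = 0; i < d * d; ++i) Q[i] = Rinv[i];
      for (int i = 0; i < d; ++i) b[i] = 0.0;
      double a_full[3];
      for (int j = 0; j < J; ++j) {
        int idx = p * J + j;
        // node 0
        a_full[0] = -ath[j]; a_full[1] = 0.0; a_full[2] = -amrs[j * 4 + c];
        double off = -beta[(j * 3 + 0) * 4 + c];
        double w = w0[idx], kap = y0[idx] - 0.5;
        for (int i = 0; i < d; ++i) {
          double ai = a_full[act[i]];
          if (ai == 0.0) continue;
          b[i] += ai * (kap - w * off);
          for (int j2 = 0; j2 < d; ++j2) Q[i * d + j2] += w * ai * a_full[act[j2]];
        }
        // node 1
        if (obs1[idx]) {
          a_full[0] = -ath[j]; a_full[1] = 0.0; a_full[2] = amrs[j * 4 + c];
          off = -beta[(j * 3 + 1) * 4 + c];
          w = w1[idx]; kap = y1[idx] - 0.5;
          for (int i = 0; i < d; ++i) {
            double ai = a_full[act[i]];
            if (ai == 0.0) continue;
            b[i] += ai * (kap - w * off);
            for (int j2 = 0; j2 < d; ++j2) Q[i * d + j2] += w * ai * a_full[act[j2]];
          }
        }
        // node 2
        if (obs2[idx]) {
          a_full[0] = sgn[idx] * omega * ath[j];
          a_full[1] = aers[j * 4 + c]; a_full[2] = 0.0;
          off = -beta[(j * 3 + 2) * 4 + c];
          w = w2[idx]; kap = y2[idx] - 0.5;
          for (int i = 0; i < d; ++i) {
            double ai = a_full[act[i]];
            if (ai == 0.0) continue;
            b[i] += ai * (kap - w * off);
            for (int j2 = 0; j2 < d; ++j2) Q[i * d + j2] += w * ai * a_full[act[j2]];
          }
        }
      }
      double x[3];
      mvn_precision_draw(Q, b, x, d);
      eta[p * 3] = 0.0; eta[p * 3 + 1] = 0.0; eta[p * 3 + 2] = 0.0;
      for (int i = 0; i < d; ++i) eta[p * 3 + act[i]] = x[i];
    }

    // -- item parameters ---------------------------------------------------
    const double lprec = 1.0 / loading_var, bprec = 1.0 / beta_var;
    for (int j = 0; j < J; ++j) {
      // node difficulties, per active class
      for (int ci = 0; ci < nclass; ++ci) {
        int c = classes0[ci];
        for (int k = 0; k < 3; ++k) {
          double sw = 0.0, su = 0.0;
          for (size_t mi = 0; mi < members[c].size(); ++mi) {
            int p = members[c][mi];
            int idx = p * J + j;
            double w, u, kap;
            if (k == 0) {
              w = w0[idx]; kap = y0[idx] - 0.5;
              u = -ath[j] * eta[p * 3] - amrs[j * 4 + c] * eta[p * 3 + 2];
            } else if (k == 1) {
              if (!obs1[idx]) continue;
              w = w1[idx]; kap = y1[idx] - 0.5;
              u = -ath[j] * eta[p * 3] + amrs[j * 4 + c] * eta[p * 3 + 2];
            } else {
              if (!obs2[idx]) continue;
              w = w2[idx]; kap = y2[idx] - 0.5;
              u = sgn[idx] * omega * ath[j] * eta[p * 3] +
                  aers[j * 4 + c] * eta[p * 3 + 1];
            }
            sw += w;
            su += w * u - kap;
          }
          double tau = bprec + sw;
          double mean = su / tau;
          beta[(j * 3 + k) * 4 + c] = mean + ::norm_rand() / std::sqrt(tau);
        }
        // ERS loading
        if (Masks::ers(c)) {
          double sxx = 0.0, sxy = 0.0;
          for (size_t mi = 0; mi < members[c].size(); ++mi) {
            int p = members[c][mi];
            int idx = p * J + j;
            if (!obs2[idx]) continue;
            double x = eta[p * 3 + 1];
            double r = sgn[idx] * omega * ath[j] * eta[p * 3] -
                       beta[(j * 3 + 2) * 4 + c];
            sxx += w2[idx] * x * x;
            sxy += x * ((y2[idx] - 0.5) - w2[idx] * r);
          }
          double tau = lprec + sxx;
          aers[j * 4 + c] = rtnorm_pos(sxy / tau, 1.0 / std::sqrt(tau));
        }
        // MRS loading (nodes 0 and 1)
        if (Masks::mrs(c)) {
          double sxx = 0.0, sxy = 0.0;
          for (size_t mi = 0; mi < members[c].size(); ++mi) {
            int p = members[c][mi];
            int idx = p * J + j;
            double x0 = -eta[p * 3 + 2];
            double r0 = -ath[j] * eta[p * 3] - beta[(j * 3 + 0) * 4 + c];
            sxx += w0[idx] * x0 * x0;
            sxy += x0 * ((y0[idx] - 0.5) - w0[idx] * r0);
            if (obs1[idx]) {
              double x1 = eta[p * 3 + 2];
              double r1 = -ath[j] * eta[p * 3] - beta[(j * 3 + 1) * 4 + c];
              sxx += w1[idx] * x1 * x1;
              sxy += x1 * ((y1[idx] - 0.5) - w1[idx] * r1);
            }
          }
          double tau = lprec + sxx;
          amrs[j * 4 + c] = rtnorm_pos(sxy / tau, 1.0 / std::sqrt(tau));
        }
      }
      // substantive loading, class-invariant: all persons, all nodes
      {
        double sxx = 0.0, sxy = 0.0;
        for (int p = 0; p < P; ++p) {
          int c = z[p];
          int idx = p * J + j;
          double th = eta[p * 3];
          double x0 = -th;
          double r0 = -amrs[j * 4 + c] * eta[p * 3 + 2] -
                      beta[(j * 3 + 0) * 4 + c];
          sxx += w0[idx] * x0 * x0;
          sxy += x0 * ((y0[idx] - 0.5) - w0[idx] * r0);
          if (obs1[idx]) {
            double r1 = amrs[j * 4 + c] * eta[p * 3 + 2] -
                        beta[(j * 3 + 1) * 4 + c];
            sxx += w1[idx] * x0 * x0;
            sxy += x0 * ((y1[idx] - 0.5) - w1[idx] * r1);
          }
          if (obs2[idx]) {
            double x2 = sgn[idx] * omega * th;
            double r2 = aers[j * 4 + c] * eta[p * 3 + 1] -
                        beta[(j * 3 + 2) * 4 + c];
            sxx += w2[idx] * x2 * x2;
            sxy += x2 * ((y2[idx] - 0.5) - w2[idx] * r2);
          }
        }
        double tau = lprec + sxx;
        ath[j] = rtnorm_pos(sxy / tau, 1.0 / std::sqrt(tau));
      }
    }

    // -- proportionality constant omega (uniform prior on [lo, hi]) --------
    {
      double sxx = 0.0, sxy = 0.0;
      for (int p = 0; p < P; ++p) {
        int c = z[p];
        double th = eta[p * 3];
        for (int j = 0; j < J; ++j) {
          int idx = p * J + j;
          if (!obs2[idx]) continue;
          double x = sgn[idx] * ath[j] * th;
          double r = aers[j * 4 + c] * eta[p * 3 + 1] -
                     beta[(j * 3 + 2) * 4 + c];
          sxx += w2[idx] * x * x;
          sxy += x * ((y2[idx] - 0.5) - w2[idx] * r);
        }
      }
      if (sxx > 0.0) {
        omega = rtnorm_interval(sxy / sxx, 1.0 / std::sqrt(sxx),
                                omega_lo, omega_hi);
      } else {
        omega = omega_lo + ::unif_rand() * (omega_hi - omega_lo);
      }
    }

    // -- trait correlations (random-walk Metropolis, PD-rejected) ----------
    if (d > 1) {
      // scatter matrix of active traits
      double S[9];
      for (int i = 0; i < d * d; ++i) S[i] = 0.0;
      for (int p = 0; p < P; ++p) {
        for (int i = 0; i < d; ++i) {
          for (int j2 = 0; j2 < d; ++j2) {
            S[i * d + j2] += eta[p * 3 + act[i]] * eta[p * 3 + act[j2]];
          }
        }
      }
      auto neg2ll = [&](const double* Rc) {
        double Lc[9], Rci[9];
        if (!chol3(Rc, Lc, d)) return 1e301;
        inv_from_chol(Lc, Rci, d);
        double ldet = 0.0, tr = 0.0;
        for (int i = 0; i < d; ++i) ldet += 2.0 * std::log(Lc[i * d + i]);
        for (int i = 0; i < d * d; ++i) tr += Rci[i] * S[i];
        return P * ldet + tr;
      };
      double cur = neg2ll(Rm);
      for (int sweep = 0; sweep < 8; ++sweep) {
      for (size_t q = 0; q < cor_pairs.size(); ++q) {
        int i = cor_pairs[q].first, j2 = cor_pairs[q].second;
        double prop = Rm[i * d + j2] + cor_prop_sd * ::norm_rand();
        ++cor_try;
        if (prop <= -1.0 || prop >= 1.0) continue;
        double Rp[9];
        for (int t = 0; t < d * d; ++t) Rp[t] = Rm[t];
        Rp[i * d + j2] = Rp[j2 * d + i] = prop;
        double cand = neg2ll(Rp);
        if (cand > 1e300) continue;  // non-PD proposal has prior mass 0
        if (std::log(::unif_rand()) <= -0.5 * (cand - cur)) {
          Rm[i * d + j2] = Rm[j2 * d + i] = prop;
          cur = cand;
          ++cor_accept;
        }
      }
      }
      if (!chol3(Rm, Lchol, d)) stop("correlation update lost PD");
      inv_from_chol(Lchol, Rinv, d);
    }

    // -- class memberships and proportions ---------------------------------
    // Updated after the parameter updates so that a warm start (z held
    // fixed for the first n_fix_z iterations) lets the class-specific
    // parameters adapt to the initial partition before reassignment.
    if (mixture) {
      if (iter >= n_fix_z) {
        for (int p = 0; p < P; ++p) {
          double ll[4], mx = -1e300;
          for (int ci = 0; ci < nclass; ++ci) {
            int c = classes0[ci];
            double s = std::log(pi[c] > 1e-300 ? pi[c] : 1e-300);
            for (int j = 0; j < J; ++j) s += cell_ll(p, j, c);
            ll[ci] = s;
            if (s > mx) mx = s;
          }
          double tot = 0.0, pr[4];
          for (int ci = 0; ci < nclass; ++ci) {
            pr[ci] = std::exp(ll[ci] - mx);
            tot += pr[ci];
          }
          double u = ::unif_rand() * tot, acc = 0.0;
          int pick = nclass - 1;
          for (int ci = 0; ci < nclass; ++ci) {
            acc += pr[ci];
            if (u <= acc) { pick = ci; break; }
          }
          z[p] = classes0[pick];
        }
      }
      // Dirichlet conditional for pi
      double g[4], gs = 0.0;
      int cnt[4] = {0, 0, 0, 0};
      for (int p = 0; p < P; ++p) ++cnt[z[p]];
      for (int c = 0; c < 4; ++c) {
        g[c] = ::Rf_rgamma(dir_alpha[c] + cnt[c], 1.0);
        gs += g[c];
      }
      for (int c = 0; c < 4; ++c) pi[c] = g[c] / gs;
    }

    // -- deviance at the current draw --------------------------------------
    double dev = 0.0;
    for (int p = 0; p < P; ++p) {
      int c = z[p];
      for (int j = 0; j < J; ++j) dev += cell_ll(p, j, c);
    }
    dev *= -2.0;

    // -- record -------------------------------------------------------------
    int col = 0;
    for (int j = 0; j < J; ++j) draws(iter, col++) = ath[j];
    draws(iter, col++) = omega;
    for (int ci = 0; ci < nclass; ++ci) {
      int c = classes0[ci];
      if (!Masks::ers(c)) continue;
      for (int j = 0; j < J; ++j) draws(iter, col++) = aers[j * 4 + c];
    }
    for (int ci = 0; ci < nclass; ++ci) {
      int c = classes0[ci];
      if (!Masks::mrs(c)) continue;
      for (int j = 0; j < J; ++j) draws(iter, col++) = amrs[j * 4 + c];
    }
    for (int ci = 0; ci < nclass; ++ci) {
      int c = classes0[ci];
      for (int k = 0; k < 3; ++k) {
        for (int j = 0; j < J; ++j) {
          draws(iter, col++) = beta[(j * 3 + k) * 4 + c];
        }
      }
    }
    for (size_t q = 0; q < cor_pairs.size(); ++q) {
      draws(iter, col++) = Rm[cor_pairs[q].first * d + cor_pairs[q].second];
    }
    if (mixture) {
      for (int c = 0; c < 4; ++c) draws(iter, col++) = pi[c];
    }
    draws(iter, col++) = dev;

    if (iter >= n_burn) {
      int it2 = iter - n_burn;
      for (int p = 0; p < P; ++p) {
        for (int t = 0; t < 3; ++t) {
          eta_sum[p * 3 + t] += eta[p * 3 + t];
          eta_ss[p * 3 + t] += eta[p * 3 + t] * eta[p * 3 + t];
        }
        pz_count[p * 4 + z[p]] += 1.0;
        if (store_z && mixture) z_draws(it2, p) = z[p] + 1;
      }
    }
  }

  NumericMatrix eta_mean(P, 3), eta_sd(P, 3), pz(P, 4);
  for (int p = 0; p < P; ++p) {
    for (int t = 0; t < 3; ++t) {
      double m = eta_sum[p * 3 + t] / n_keep;
      eta_mean(p, t) = m;
      double v = eta_ss[p * 3 + t] / n_keep - m * m;
      eta_sd(p, t) = v > 0 ? std::sqrt(v * n_keep / (n_keep - 1.0)) : 0.0;
    }
    for (int c = 0; c < 4; ++c) pz(p, c) = pz_count[p * 4 + c] / n_keep;
  }

  // final state, usable to warm-start another chain
  NumericMatrix eta_out(P, 3), R_out(3, 3), aers_out(J, 4), amrs_out(J, 4);
  IntegerVector z_out(P);
  NumericVector ath_out(J), pi_out(4), beta_out(J * 3 * 4);
  for (int p = 0; p < P; ++p) {
    z_out[p] = z[p] + 1;
    for (int t = 0; t < 3; ++t) eta_out(p, t) = eta[p * 3 + t];
  }
  for (int j = 0; j < J; ++j) {
    ath_out[j] = ath[j];
    for (int c = 0; c < 4; ++c) {
      aers_out(j, c) = aers[j * 4 + c];
      amrs_out(j, c) = amrs[j * 4 + c];
      for (int k = 0; k < 3; ++k) {
        beta_out[j + J * k + J * 3 * c] = beta[(j * 3 + k) * 4 + c];
      }
    }
  }
  for (int c = 0; c < 4; ++c) pi_out[c] = pi[c];
  R_out.fill(0.0);
  for (int t = 0; t < 3; ++t) R_out(t, t) = 1.0;
  for (int i = 0; i < d; ++i) {
    for (int j2 = 0; j2 < d; ++j2) R_out(act[i], act[j2]) = Rm[i * d + j2];
  }
  beta_out.attr("dim") = IntegerVector::create(J, 3, 4);
  List state = List::create(
      _["z"] = z_out, _["eta"] = eta_out, _["pi"] = pi_out, _["R"] = R_out,
      _["items"] = List::create(_["ath"] = ath_out, _["omega"] = omega,
                                _["aers"] = aers_out, _["amrs"] = amrs_out,
                                _["beta"] = beta_out));

  return List::create(
      _["draws"] = draws, _["z"] = z_draws, _["pz"] = pz,
      _["eta_mean"] = eta_mean, _["eta_sd"] = eta_sd, _["state"] = state,
      _["cor_accept_rate"] = cor_try > 0 ? (double)cor_accept / cor_try : NA_REAL);
}

// [[Rcpp::export]]
NumericVector rpg_vec(NumericVector psi) {
  RNGScope scope;
  int n = psi.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = pg::rpg1(psi[i]);
  return out;
}
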