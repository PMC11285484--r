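#include <Rcpp.h>
#include <cmath>
#include "socdisc.h"
using namespace Rcpp;

// One MCMC chain for the hierarchical drift-diffusion model.
//
// Subject-level parameters live on transformed scales:
//   th0 -> alpha = exp(th0)                boundary separation
//   th1 -> beta  = plogis(th1)             start bias
//   th2 -> delta = th2                     drift
//   th3 -> tau   = lb + plogis(th3)*(ub_i - lb)   non-decision time,
//          lb the global reaction-time floor, ub_i = 0.95 * min observed rt
// For each transformed parameter p, subject i:
//   th[i,p] ~ Normal(mu_p + b_p'x_i, sd_p),  x_i = (sex, condition, sex*cond)
// Priors: mu_p, b_p ~ Normal(0,1); sd_p ~ half-Normal(1).
//
// Updates: adaptive random-walk Metropolis for each th[i,p] and each log sd_p
// (acceptance tuned to ~0.44 during warmup), exact Gibbs draw for the
// regression coefficients (mu_p, b_p) given subject parameters and sd_p.

static inline double plogis_(double x) { return 1.0 / (1.0 + std::exp(-x)); }

static double subject_ll(const NumericVector& rt, const IntegerVector& up,
                         int lo, int hi, double th0, double th1, double th2,
                         double th3, double rt_lb, double tau_ub, double eps) {
  double a = std::exp(th0);
  double w = plogis_(th1);
  double v = th2;
  double tau = rt_lb + plogis_(th3) * (tau_ub - rt_lb);
  double ll = 0.0;
  for (int j = lo; j <= hi; ++j) {
    double t = rt[j] - tau;
    double l = (up[j] == 1) ? wiener_lpdf_lower(t, a, -v, 1.0 - w, eps)
                            : wiener_lpdf_lower(t, a, v, w, eps);
    if (!R_finite(l)) return R_NegInf;
    ll += l;
  }
  return ll;
}

// Cholesky of a 4x4 SPD matrix (lower), solve and sampling helpers.
static void chol4(const double A[4][4], double L[4][4]) {
  for (int i = 0; i < 4; ++i)
    for (int j = 0; j <= i; ++j) {
      double s = A[i][j];
      for (int k = 0; k < j; ++k) s -= L[i][k] * L[j][k];
      if (i == j) L[i][i] = std::sqrt(s);
      else L[i][j] = s / L[j][j];
    }
}

// [[Rcpp::export(name = ".ddm_mcmc_chain")]]
List ddm_mcmc_chain(NumericVector rt, IntegerVector upper,
                    IntegerVector sub_lo, IntegerVector sub_hi,
                    NumericMatrix X, NumericVector tau_ub,
                    int iter, int warmup, NumericMatrix theta_init,
                    NumericVector mu_init, NumericMatrix b_init,
                    NumericVector sd_init, double rt_lb, double eps,
                    int sweeps) {
  int nsub = sub_lo.size();
  int nkeep = iter - warmup;
  if (nkeep <= 0) stop("iter must exceed warmup");

  // state
  NumericMatrix th(clone(theta_init));        // nsub x 4
  double mu[4], b[4][3], sd[4];
  for (int p = 0; p < 4; ++p) {
    mu[p] = mu_init[p];
    sd[p] = sd_init[p];
    for (int c = 0; c < 3; ++c) b[p][c] = b_init(p, c);
  }

  std::vector<double> cur_ll(nsub);
  for (int i = 0; i < nsub; ++i)
    cur_ll[i] = subject_ll(rt, upper, sub_lo[i], sub_hi[i], th(i, 0), th(i, 1),
                           th(i, 2), th(i, 3), rt_lb, tau_ub[i], eps);

  // proposal scales + batch acceptance counters
  NumericMatrix ps(nsub, 4);
  std::fill(ps.begin(), ps.end(), 0.15);
  NumericMatrix acc(nsub, 4);
  double ps_sd[4] = {0.2, 0.2, 0.2, 0.2}, acc_sd[4] = {0, 0, 0, 0};
  double ps_sh[4][4], acc_sh[4][4], ps_sc[4], acc_sc[4];
  for (int p = 0; p < 4; ++p) {
    ps_sc[p] = 0.2; acc_sc[p] = 0.0;
    for (int c = 0; c < 4; ++c) { ps_sh[p][c] = 0.1; acc_sh[p][c] = 0.0; }
  }
  const int batch = 50;

  // precompute Z'Z for Z = [1 X]
  double ZtZ[4][4] = {{0}};
  for (int i = 0; i < nsub; ++i) {
    double z[4] = {1.0, X(i, 0), X(i, 1), X(i, 2)};
    for (int r = 0; r < 4; ++r)
      for (int c = 0; c < 4; ++c) ZtZ[r][c] += z[r] * z[c];
  }

  NumericMatrix group_draws(nkeep, 20);   // per p: mu, b1, b2, b3, sd
  NumericMatrix subj_draws(nkeep, nsub * 4);

  for (int it = 0; it < iter; ++it) {
    // subject-level Metropolis updates (several sweeps per iteration to
    // cut the autocorrelation of the random walk)
    for (int sw = 0; sw < sweeps; ++sw)
    for (int p = 0; p < 4; ++p) {
      for (int i = 0; i < nsub; ++i) {
        double m = mu[p] + b[p][0] * X(i, 0) + b[p][1] * X(i, 1) +
                   b[p][2] * X(i, 2);
        double old = th(i, p);
        double prop = old + ps(i, p) * norm_rand();
        double t0 = th(i, 0), t1 = th(i, 1), t2 = th(i, 2), t3 = th(i, 3);
        if (p == 0) t0 = prop; else if (p == 1) t1 = prop;
        else if (p == 2) t2 = prop; else t3 = prop;
        double ll_new = subject_ll(rt, upper, sub_lo[i], sub_hi[i], t0, t1, t2,
                                   t3, rt_lb, tau_ub[i], eps);
        double lr = ll_new - cur_ll[i] +
                    R::dnorm(prop, m, sd[p], 1) - R::dnorm(old, m, sd[p], 1);
        if (R_finite(ll_new) && std::log(unif_rand()) < lr) {
          th(i, p) = prop;
          cur_ll[i] = ll_new;
          acc(i, p) += 1.0;
        }
      }
    }

    // group-level updates per parameter family
    for (int p = 0; p < 4; ++p) {
      // Gibbs for (mu_p, b_p): posterior precision A = Z'Z/sd^2 + I
      double s2 = sd[p] * sd[p];
      double A[4][4], L[4][4];
      for (int r = 0; r < 4; ++r)
        for (int c = 0; c < 4; ++c)
          A[r][c] = ZtZ[r][c] / s2 + (r == c ? 1.0 : 0.0);
      double rhs[4] = {0, 0, 0, 0};
      for (int i = 0; i < nsub; ++i) {
        double z[4] = {1.0, X(i, 0), X(i, 1), X(i, 2)};
        for (int r = 0; r < 4; ++r) rhs[r] += z[r] * th(i, p) / s2;
      }
      chol4(A, L);
      // mean: solve A m = rhs via L L' m = rhs
      double y[4], mvec[4];
      for (int r = 0; r < 4; ++r) {
        double s = rhs[r];
        for (int k = 0; k < r; ++k) s -= L[r][k] * y[k];
        y[r] = s / L[r][r];
      }
      for (int r = 3; r >= 0; --r) {
        double s = y[r];
        for (int k = r + 1; k < 4; ++k) s -= L[k][r] * mvec[k];
        mvec[r] = s / L[r][r];
      }
      // draw: m + L'^{-1} z
      double zr[4], dr[4];
      for (int r = 0; r < 4; ++r) zr[r] = norm_rand();
      for (int r = 3; r >= 0; --r) {
        double s = zr[r];
        for (int k = r + 1; k < 4; ++k) s -= L[k][r] * dr[k];
        dr[r] = s / L[r][r];
      }
      mu[p] = mvec[0] + dr[0];
      for (int c = 0; c < 3; ++c) b[p][c] = mvec[c + 1] + dr[c + 1];

      // Metropolis on log sd_p, half-Normal(1) prior, log Jacobian
      double lsd = std::log(sd[p]);
      double lsd_new = lsd + ps_sd[p] * norm_rand();
      double sd_new = std::exp(lsd_new);
      double lp_old = -0.5 * sd[p] * sd[p] + lsd;
      double lp_new = -0.5 * sd_new * sd_new + lsd_new;
      for (int i = 0; i < nsub; ++i) {
        double m = mu[p] + b[p][0] * X(i, 0) + b[p][1] * X(i, 1) +
                   b[p][2] * X(i, 2);
        lp_old += R::dnorm(th(i, p), m, sd[p], 1);
        lp_new += R::dnorm(th(i, p), m, sd_new, 1);
      }
      if (std::log(unif_rand()) < lp_new - lp_old) {
        sd[p] = sd_new;
        acc_sd[p] += 1.0;
      }
    }

    // independence proposals from the conditional prior: where the
    // likelihood plateaus (e.g. a saturated non-decision-time
    // transform) the conditional posterior reduces to the prior and
    // these moves jump across the plateau in one step
    for (int p = 0; p < 4; ++p) {
      for (int i = 0; i < nsub; ++i) {
        double m = mu[p] + b[p][0] * X(i, 0) + b[p][1] * X(i, 1) +
                   b[p][2] * X(i, 2);
        double prop = m + sd[p] * norm_rand();
        double t0 = th(i, 0), t1 = th(i, 1), t2 = th(i, 2), t3 = th(i, 3);
        if (p == 0) t0 = prop; else if (p == 1) t1 = prop;
        else if (p == 2) t2 = prop; else t3 = prop;
        double ll_new = subject_ll(rt, upper, sub_lo[i], sub_hi[i], t0, t1,
                                   t2, t3, rt_lb, tau_ub[i], eps);
        // prior terms cancel against the proposal density
        if (R_finite(ll_new) &&
            std::log(unif_rand()) < ll_new - cur_ll[i]) {
          th(i, p) = prop;
          cur_ll[i] = ll_new;
        }
      }
    }

    // interweaved (non-centered) moves: joint shifts of one group
    // coefficient together with its subjects' parameters, and a joint
    // rescale of (sd_p, subject residuals). These traverse the
    // prior-dominated directions (e.g. a saturated non-decision-time
    // transform) that single-site updates cross slowly.
    for (int p = 0; p < 4; ++p) {
      for (int c = 0; c < 4; ++c) {  // c=0 grand mean, 1..3 coefficients
        double epsl = ps_sh[p][c] * norm_rand();
        double cur = (c == 0) ? mu[p] : b[p][c - 1];
        double lr = R::dnorm(cur + epsl, 0.0, 1.0, 1) -
                    R::dnorm(cur, 0.0, 1.0, 1);
        std::vector<double> ll_new(nsub, 0.0);
        bool finite = true;
        for (int i = 0; i < nsub && finite; ++i) {
          double zi = (c == 0) ? 1.0 : X(i, c - 1);
          if (zi == 0.0) { ll_new[i] = cur_ll[i]; continue; }
          double t0 = th(i, 0), t1 = th(i, 1), t2 = th(i, 2), t3 = th(i, 3);
          if (p == 0) t0 += zi * epsl; else if (p == 1) t1 += zi * epsl;
          else if (p == 2) t2 += zi * epsl; else t3 += zi * epsl;
          ll_new[i] = subject_ll(rt, upper, sub_lo[i], sub_hi[i], t0, t1,
                                 t2, t3, rt_lb, tau_ub[i], eps);
          if (!R_finite(ll_new[i])) finite = false;
          lr += ll_new[i] - cur_ll[i];
        }
        if (finite && std::log(unif_rand()) < lr) {
          if (c == 0) mu[p] += epsl; else b[p][c - 1] += epsl;
          for (int i = 0; i < nsub; ++i) {
            double zi = (c == 0) ? 1.0 : X(i, c - 1);
            if (zi == 0.0) continue;
            th(i, p) += zi * epsl;
            cur_ll[i] = ll_new[i];
          }
          acc_sh[p][c] += 1.0;
        }
      }
      // scale move: sd' = g*sd, residuals scaled by g; the subject-prior
      // density ratio cancels against the transform Jacobian
      {
        double eta = ps_sc[p] * norm_rand();
        double g = std::exp(eta);
        double sd_new = sd[p] * g;
        double lr = (-sd_new * sd_new + sd[p] * sd[p]) / 2.0 + eta;
        std::vector<double> ll_new(nsub, 0.0);
        std::vector<double> th_new(nsub, 0.0);
        bool finite = true;
        for (int i = 0; i < nsub && finite; ++i) {
          double m = mu[p] + b[p][0] * X(i, 0) + b[p][1] * X(i, 1) +
                     b[p][2] * X(i, 2);
          th_new[i] = m + g * (th(i, p) - m);
          double t0 = th(i, 0), t1 = th(i, 1), t2 = th(i, 2), t3 = th(i, 3);
          if (p == 0) t0 = th_new[i]; else if (p == 1) t1 = th_new[i];
          else if (p == 2) t2 = th_new[i]; else t3 = th_new[i];
          ll_new[i] = subject_ll(rt, upper, sub_lo[i], sub_hi[i], t0, t1,
                                 t2, t3, rt_lb, tau_ub[i], eps);
          if (!R_finite(ll_new[i])) finite = false;
          lr += ll_new[i] - cur_ll[i];
        }
        if (finite && std::log(unif_rand()) < lr) {
          sd[p] = sd_new;
          for (int i = 0; i < nsub; ++i) {
            th(i, p) = th_new[i];
            cur_ll[i] = ll_new[i];
          }
          acc_sc[p] += 1.0;
        }
      }
    }

    // proposal adaptation during warmup
    if (it < warmup && (it + 1) % batch == 0) {
      for (int p = 0; p < 4; ++p) {
        for (int i = 0; i < nsub; ++i) {
          double rate = acc(i, p) / (batch * sweeps);
          ps(i, p) *= std::exp(0.6 * (rate - 0.44));
          acc(i, p) = 0.0;
        }
        double rate = acc_sd[p] / batch;
        ps_sd[p] *= std::exp(0.6 * (rate - 0.44));
        acc_sd[p] = 0.0;
        for (int c = 0; c < 4; ++c) {
          rate = acc_sh[p][c] / batch;
          ps_sh[p][c] *= std::exp(0.6 * (rate - 0.44));
          acc_sh[p][c] = 0.0;
        }
        rate = acc_sc[p] / batch;
        ps_sc[p] *= std::exp(0.6 * (rate - 0.44));
        acc_sc[p] = 0.0;
      }
    }

    if (it >= warmup) {
      int r = it - warmup;
      for (int p = 0; p < 4; ++p) {
        group_draws(r, 5 * p) = mu[p];
        for (int c = 0; c < 3; ++c) group_draws(r, 5 * p + 1 + c) = b[p][c];
        group_draws(r, 5 * p + 4) = sd[p];
      }
      for (int i = 0; i < nsub; ++i)
        for (int p = 0; p < 4; ++p) subj_draws(r, 4 * i + p) = th(i, p);
    }
  }

  return List::create(_["group"] = group_draws, _["subject"] = subj_draws);
}
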