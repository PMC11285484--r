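#include <Rcpp.h>
#include <cmath>
#include "socdisc.h"
using namespace Rcpp;

// Density of the normalized (a = 1, v = 0) first passage through the lower
// boundary at normalized time tt, start w. Small-time and large-time series;
// term counts follow the usual truncation bounds for tolerance eps, and the
// cheaper expansion is used.
static double fpt_density_norm(double tt, double w, double eps) {
  double ks, kl;
  if (2.0 * std::sqrt(2.0 * M_PI * tt) * eps < 1.0) {
    ks = 2.0 + std::sqrt(-2.0 * tt *
                         std::log(2.0 * eps * std::sqrt(2.0 * M_PI * tt)));
    ks = std::max(ks, std::sqrt(tt) + 1.0);
  } else {
    ks = 2.0;
  }
  if (M_PI * tt * eps < 1.0) {
    kl = std::sqrt(-2.0 * std::log(M_PI * tt * eps) / (M_PI * M_PI * tt));
    kl = std::max(kl, 1.0 / (M_PI * std::sqrt(tt)));
  } else {
    kl = 1.0 / (M_PI * std::sqrt(tt));
  }

  double p = 0.0;
  if (ks < kl) {  // small-time expansion
    int K = (int)std::ceil(ks);
    int lo = -((K - 1) / 2), hi = (K - 1) / 2 + ((K - 1) % 2);
    for (int k = lo; k <= hi; ++k) {
      double z = w + 2.0 * k;
      p += z * std::exp(-z * z / (2.0 * tt));
    }
    p /= std::sqrt(2.0 * M_PI * tt * tt * tt);
  } else {        // large-time expansion
    int K = (int)std::ceil(kl);
    for (int k = 1; k <= K; ++k) {
      p += k * std::exp(-k * k * M_PI * M_PI * tt / 2.0) *
           std::sin(k * M_PI * w);
    }
    p *= M_PI;
  }
  return p;
}

double wiener_lpdf_lower(double t, double a, double v, double w, double eps) {
  if (!(t > 0.0) || !(a > 0.0) || !(w > 0.0) || !(w < 1.0)) return R_NegInf;
  double tt = t / (a * a);
  double p = fpt_density_norm(tt, w, eps);
  if (!(p > 0.0)) return R_NegInf;  // series round-off below machine floor
  return std::log(p) - 2.0 * std::log(a) - v * a * w - v * v * t / 2.0;
}

//' @noRd
// [[Rcpp::export(name = ".wiener_lpdf_cpp")]]
NumericVector wiener_lpdf_cpp(NumericVector rt, IntegerVector upper,
                              double alpha, double beta, double delta,
                              double tau, double eps) {
  int n = rt.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double t = rt[i] - tau;
    if (upper[i] == 1) {
      out[i] = wiener_lpdf_lower(t, alpha, -delta, 1.0 - beta, eps);
    } else {
      out[i] = wiener_lpdf_lower(t, alpha, delta, beta, eps);
    }
  }
  return out;
}

// Euler-Maruyama simulation of the diffusion with optional Brownian-bridge
// crossing correction within each step (removes most of the O(sqrt(dt))
// boundary-overshoot bias). Returns boundary (1 upper, 0 lower, NA if tmax
// exceeded) and rt (hitting time + tau, NA on timeout).
//' @noRd
// [[Rcpp::export(name = ".ddm_sim_cpp")]]
List ddm_sim_cpp(int n, double alpha, double beta, double delta, double tau,
                 double dt, double tmax, bool bridge) {
  if (dt <= 0.0) stop("step size must be positive");
  IntegerVector boundary(n);
  NumericVector rt(n);
  double sdt = std::sqrt(dt);
  for (int i = 0; i < n; ++i) {
    double x = beta * alpha, t = 0.0;
    int b = NA_INTEGER;
    while (t < tmax) {
      double xn = x + delta * dt + sdt * norm_rand();
      t += dt;
      if (xn >= alpha) { b = 1; break; }
      if (xn <= 0.0)   { b = 0; break; }
      if (bridge) {
        // probability the bridge between x and xn crossed a boundary
        double pu = std::exp(-2.0 * (alpha - x) * (alpha - xn) / dt);
        if (unif_rand() < pu) { b = 1; break; }
        double pl = std::exp(-2.0 * x * xn / dt);
        if (unif_rand() < pl) { b = 0; break; }
      }
      x = xn;
    }
    boundary[i] = b;
    rt[i] = (b == NA_INTEGER) ? NA_REAL : t + tau;
  }
  return List::create(_["boundary"] = boundary, _["rt"] = rt);
}
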