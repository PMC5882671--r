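#include <Rcpp.h>
using namespace Rcpp;

// First-passage-time machinery for the Wiener diffusion between two
// absorbing boundaries (diffusion coefficient s = 1 throughout).
//
// The defective density of hitting the LOWER boundary at decision time t,
// for threshold separation a, relative start w in (0,1) and drift v, is
//
//   f_lower(t) = (1/a^2) * exp(-v*a*w - v^2 t / 2) * f1(t/a^2; w)
//
// where f1(u; w) is the zero-drift unit-scale density, available as a
// small-time or a large-time series.  With normally distributed
// across-trial drift, v ~ N(mu, sv^2), the drift-dependent factor
// integrates in closed form and only the multiplier changes.

// f1(u; w): zero-drift density at scaled time u, start w, lower boundary.
// method: 0 = auto (pick cheaper series), 1 = force small-time,
//         2 = force large-time.  eps is the target absolute error on f1.
static double fpt_f1(double u, double w, double eps, int method) {
  // term counts after Navarro & Fuss (2009)
  double ks, kl;
  if (2.0 * std::sqrt(2.0 * M_PI * u) * eps < 1.0) {
    ks = 2.0 + std::sqrt(-2.0 * u * std::log(2.0 * eps * std::sqrt(2.0 * M_PI * u)));
    ks = std::max(ks, std::sqrt(u) + 1.0);
  } else {
    ks = 2.0;
  }
  if (M_PI * u * eps < 1.0) {
    kl = std::sqrt(-2.0 * std::log(M_PI * u * eps) / (M_PI * M_PI * u));
    kl = std::max(kl, 1.0 / (M_PI * std::sqrt(u)));
  } else {
    kl = 1.0 / (M_PI * std::sqrt(u));
  }

  bool small_time = (method == 1) || (method == 0 && ks < kl);
  double p = 0.0;
  if (small_time) {
    int K = (int)std::ceil(ks);
    int lo = -(int)std::floor((K - 1) / 2.0);
    int hi = (int)std::ceil((K - 1) / 2.0);
    for (int k = lo; k <= hi; ++k) {
      double wk = w + 2.0 * k;
      p += wk * std::exp(-wk * wk / (2.0 * u));
    }
    p /= std::sqrt(2.0 * M_PI * u * u * u);
  } else {
    int K = (int)std::ceil(kl);
    for (int k = 1; k <= K; ++k) {
      p += k * std::exp(-k * k * M_PI * M_PI * u / 2.0) * std::sin(k * M_PI * w);
    }
    p *= M_PI;
  }
  return p > 0.0 ? p : 0.0;
}

static double dwiener_one(double t, double a, double w, double v, double sv,
                          bool upper, double eps, int method) {
  if (!(t > 0.0)) return 0.0;
  if (upper) {  // mirror: upper(a, w, v) == lower(a, 1 - w, -v)
    w = 1.0 - w;
    v = -v;
  }
  double mult;
  if (sv > 0.0) {
    double sv2 = sv * sv;
    double den = 1.0 + sv2 * t;
    mult = std::exp((sv2 * a * a * w * w - 2.0 * v * a * w - v * v * t) / (2.0 * den)) /
           std::sqrt(den);
  } else {
    mult = std::exp(-v * a * w - v * v * t / 2.0);
  }
  return fpt_f1(t / (a * a), w, eps, method) * mult / (a * a);
}

// Vectorised defective first-passage density.  All parameter arguments are
// recycled against the longest input.
// [[Rcpp::export(name = ".dwiener_cpp")]]
NumericVector dwiener_cpp(NumericVector t, NumericVector a, NumericVector w,
                          NumericVector v, NumericVector sv,
                          LogicalVector upper, double eps = 1e-7,
                          int method = 0) {
  R_xlen_t n = std::max({t.size(), a.size(), w.size(), v.size(), sv.size(),
                         upper.size()});
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    out[i] = dwiener_one(t[i % t.size()], a[i % a.size()], w[i % w.size()],
                         v[i % v.size()], sv[i % sv.size()],
                         upper[i % upper.size()], eps, method);
  }
  return out;
}

// Summed log-density per column of a draws-by-trials layout: trial vectors
// of length n_trials are evaluated under m parameter rows packed
// column-major (trial fastest).  Used by the batched DE-MCMC update.
// [[Rcpp::export(name = ".wiener_loglik_batch_cpp")]]
NumericVector wiener_loglik_batch_cpp(NumericVector t, LogicalVector upper,
                                      NumericVector a, NumericVector w,
                                      NumericVector v, NumericVector t0,
                                      NumericVector sv, int n_trials,
                                      double eps = 1e-7) {
  int m = a.size() / n_trials;
  NumericVector out(m);
  for (int j = 0; j < m; ++j) {
    double s = 0.0;
    for (int i = 0; i < n_trials; ++i) {
      R_xlen_t k = (R_xlen_t)j * n_trials + i;
      double td = t[i] - t0[k];
      if (!(td > 0.0)) { s = R_NegInf; break; }
      double d = dwiener_one(td, a[k], w[k], v[k], sv[k], upper[i], eps, 0);
      if (d <= 0.0) { s = R_NegInf; break; }
      s += std::log(d);
    }
    out[j] = s;
  }
  return out;
}

// Exact-in-distribution trial simulator: within a trial the drift is
// constant, so each dt-step increment is exactly Gaussian; absorption
// between grid points is resolved by the Brownian-bridge crossing
// probability, making the hit/no-hit outcome exact in law (RT is
// discretised at dt).  v and w are per-trial vectors.
// boundary: 1 = upper, 0 = lower, NA = no response before max_t.
// [[Rcpp::export(name = ".sim_wiener_cpp")]]
List sim_wiener_cpp(NumericVector v, NumericVector w, double a, double t0,
                    double dt, double max_t) {
  R_xlen_t n = v.size();
  IntegerVector boundary(n);
  NumericVector rt(n);
  double sqdt = std::sqrt(dt);
  for (R_xlen_t i = 0; i < n; ++i) {
    double x = w[i % w.size()] * a;
    double vi = v[i];
    double tcur = 0.0;
    int b = NA_INTEGER;
    while (tcur + t0 < max_t) {
      double x1 = x + vi * dt + sqdt * R::norm_rand();
      tcur += dt;
      if (x1 >= a) { b = 1; break; }
      if (x1 <= 0.0) { b = 0; break; }
      if (R::unif_rand() < std::exp(-2.0 * (a - x) * (a - x1) / dt)) { b = 1; break; }
      if (R::unif_rand() < std::exp(-2.0 * x * x1 / dt)) { b = 0; break; }
      x = x1;
    }
    boundary[i] = b;
    rt[i] = (b == NA_INTEGER) ? NA_REAL : tcur + t0;
  }
  return List::create(_["boundary"] = boundary, _["rt"] = rt);
}
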