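// BayesB mixture-model Gibbs/Metropolis-Hastings sampler.
//
// Model: y = 1*mu + sum_j x_j a_j + e, e ~ N(0, sigma2_e I).
// Each locus j carries an indicator delta_j; with prior probability
// (1 - pi) the locus has a_j ~ N(0, sigma2_j), sigma2_j ~ scaled
// inv-chi^2(nu, S); otherwise a_j = 0 exactly. Because delta_j = 0 has
// zero prior density for sigma2_j, (delta_j, sigma2_j) is updated jointly
// by Metropolis-Hastings with a_j integrated out of the likelihood,
// proposing from the prior mixture (so the prior cancels in the ratio);
// included effects, the intercept and the residual variance then have
// conjugate Gibbs updates.
//
// Determinism/exchangeability contract: every locus owns a private
// xoshiro256++ stream seeded from (master seed, SNP id hash), and loci are
// processed in a canonical order supplied by the caller (sorted SNP id).
// Permuting genotype columns therefore permutes the output exactly.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

namespace {

struct Rng {
  uint64_t s[4];

  static uint64_t splitmix64(uint64_t &x) {
    x += 0x9E3779B97f4A7C15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }

  void seed(uint64_t v) {
    uint64_t x = v;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
  }

  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }

  uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }

  // uniform on (0,1); never exactly 0 (safe inside log())
  double unif() {
    double u = (next() >> 11) * 0x1.0p-53;
    return u > 0.0 ? u : 0x1.0p-53;
  }

  double norm() {
    double u1 = unif(), u2 = unif();
    return std::sqrt(-2.0 * std::log(u1)) * std::cos(6.283185307179586476925287 * u2);
  }

  // Marsaglia-Tsang; valid for alpha >= 1, extended below 1 by boosting.
  double gamma(double alpha) {
    if (alpha < 1.0) {
      double u = unif();
      return gamma(alpha + 1.0) * std::pow(u, 1.0 / alpha);
    }
    double d = alpha - 1.0 / 3.0;
    double c = 1.0 / std::sqrt(9.0 * d);
    for (;;) {
      double x = norm();
      double v = 1.0 + c * x;
      if (v <= 0.0) continue;
      v = v * v * v;
      double u = unif();
      if (u < 1.0 - 0.0331 * x * x * x * x) return d * v;
      if (std::log(u) < 0.5 * x * x + d * (1.0 - v + std::log(v))) return d * v;
    }
  }

  double chisq(double df) { return 2.0 * gamma(0.5 * df); }
};

uint64_t fnv1a(const char *sp) {
  uint64_t h = 1469598103934665603ULL;
  for (const char *p = sp; *p; ++p) {
    h ^= (uint64_t)(unsigned char)(*p);
    h *= 1099511628211ULL;
  }
  return h;
}

// log marginal likelihood of the residual with locus effect integrated out,
// up to terms constant in v: v = sigma2_j, r = x_j' e_{-j}, xtx = x_j' x_j.
inline double loglik_v(double v, double xtx, double r, double s2e) {
  if (v <= 0.0) return -0.5 * std::log(s2e);
  double denom = s2e + v * xtx;
  return -0.5 * std::log(denom) + 0.5 * v * r * r / (s2e * denom);
}

} // namespace

// [[Rcpp::export]]
List bayesb_mcmc_cpp(NumericMatrix X, NumericVector y, CharacterVector snp_ids,
                     IntegerVector proc_order, double one_minus_pi,
                     double nu, double s, int n_iter, int thin, int mh_inner,
                     double master_seed) {
  const int n = X.nrow(), m = X.ncol();
  if (n < 2) stop("need at least 2 animals");
  if (y.size() != n) stop("y length mismatch");
  if (one_minus_pi <= 0.0 || one_minus_pi >= 1.0) stop("one_minus_pi must lie in (0,1)");
  if (thin < 1 || n_iter < thin) stop("need n_iterations >= thin >= 1");
  const double pi_excl = 1.0 - one_minus_pi;
  const int n_rec = n_iter / thin;

  // per-locus RNG streams keyed by SNP id, plus one global stream
  std::vector<Rng> rng(m);
  for (int j = 0; j < m; ++j) {
    uint64_t hj = fnv1a(CHAR(STRING_ELT(snp_ids, j)));
    uint64_t sd = (uint64_t)master_seed;
    uint64_t mix = sd ^ (hj + 0x9E3779B97f4A7C15ULL);
    rng[j].seed(Rng::splitmix64(mix));
  }
  Rng g;
  {
    uint64_t sd = (uint64_t)master_seed;
    g.seed(Rng::splitmix64(sd) ^ 0xA5A5A5A55A5A5A5AULL);
  }

  std::vector<double> xtx(m);
  for (int j = 0; j < m; ++j) {
    const double *xj = &X(0, j);
    double acc = 0.0;
    for (int i = 0; i < n; ++i) acc += xj[i] * xj[i];
    xtx[j] = acc;
  }

  double mu = 0.0;
  for (int i = 0; i < n; ++i) mu += y[i];
  mu /= n;
  std::vector<double> e(n), a(m, 0.0), sig2(m, 0.0);
  std::vector<int> delta(m, 0);
  double sse0 = 0.0;
  for (int i = 0; i < n; ++i) { e[i] = y[i] - mu; sse0 += e[i] * e[i]; }
  double s2e = sse0 / (n - 1);
  if (s2e <= 0.0) stop("phenotype has zero variance");

  NumericMatrix rec_a(n_rec, m);
  IntegerMatrix rec_d(n_rec, m);
  NumericVector rec_s2e(n_rec), rec_mu(n_rec), rec_ll(n_rec);

  for (int it = 0; it < n_iter; ++it) {
    if ((it & 1023) == 0) Rcpp::checkUserInterrupt();

    // intercept (global stream)
    double ebar = 0.0;
    for (int i = 0; i < n; ++i) ebar += e[i];
    ebar /= n;
    double mu_new = (ebar + mu) + g.norm() * std::sqrt(s2e / n);
    double dmu = mu_new - mu;
    for (int i = 0; i < n; ++i) e[i] -= dmu;
    mu = mu_new;

    // loci, canonical order, private streams
    for (int jj = 0; jj < m; ++jj) {
      const int j = proc_order[jj];
      Rng &rj = rng[j];
      const double *xj = &X(0, j);
      double v_cur = sig2[j];
      double r = 0.0;
      bool have_r = false;
      for (int t = 0; t < mh_inner; ++t) {
        double v_prop = (rj.unif() < pi_excl) ? 0.0 : nu * s / rj.chisq(nu);
        if (v_prop == 0.0 && v_cur == 0.0) continue;
        if (!have_r) {
          double acc = 0.0;
          for (int i = 0; i < n; ++i) acc += xj[i] * e[i];
          r = acc + a[j] * xtx[j];
          have_r = true;
        }
        double lr = loglik_v(v_prop, xtx[j], r, s2e) -
                    loglik_v(v_cur, xtx[j], r, s2e);
        if (lr >= 0.0 || std::log(rj.unif()) < lr) v_cur = v_prop;
      }
      double a_old = a[j];
      if (v_cur > 0.0) {
        if (!have_r) {
          double acc = 0.0;
          for (int i = 0; i < n; ++i) acc += xj[i] * e[i];
          r = acc + a_old * xtx[j];
        }
        double prec = xtx[j] / s2e + 1.0 / v_cur;
        double mean = (r / s2e) / prec;
        double a_new = mean + rj.norm() / std::sqrt(prec);
        sig2[j] = v_cur; delta[j] = 1;
        double da = a_old - a_new;
        if (da != 0.0) for (int i = 0; i < n; ++i) e[i] += xj[i] * da;
        a[j] = a_new;
      } else {
        sig2[j] = 0.0; delta[j] = 0;
        if (a_old != 0.0) {
          for (int i = 0; i < n; ++i) e[i] += xj[i] * a_old;
          a[j] = 0.0;
        }
      }
    }

    // residual variance (flat prior -> scaled inv-chi^2(n-2, sse/(n-2)))
    double sse = 0.0;
    for (int i = 0; i < n; ++i) sse += e[i] * e[i];
    s2e = sse / g.chisq((double)(n - 2));
    if (!std::isfinite(s2e) || s2e <= 0.0)
      stop("residual variance diverged at iteration %d (sse=%g)", it + 1, sse);

    if ((it + 1) % thin == 0) {
      int rr = (it + 1) / thin - 1;
      for (int j = 0; j < m; ++j) { rec_a(rr, j) = a[j]; rec_d(rr, j) = delta[j]; }
      rec_s2e[rr] = s2e; rec_mu[rr] = mu;
      double cst = -0.5 * std::log(2.0 * M_PI * s2e);
      double ll = 0.0;
      for (int i = 0; i < n; ++i)
        ll += std::fabs(cst - e[i] * e[i] / (2.0 * s2e));
      rec_ll[rr] = ll;
    }
  }

  return List::create(_["effects"] = rec_a, _["delta"] = rec_d,
                      _["sigma2_e"] = rec_s2e, _["mu"] = rec_mu,
                      _["loglik_abs"] = rec_ll);
}
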