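// Polya-Gamma PG(b, c) random variate generation.
//
// Hybrid scheme:
//   * integer b <= PG_DEVROYE_MAX : sum of exact Devroye PG(1, c) draws
//   * fractional remainder, and 12 < b <= 170 : two-moment gamma match
//   * b > 170 : normal approximation
// A truncated sum-of-gammas series (with exact mean tail correction) is kept
// as an independent cross-check sampler.
//
// All randomness comes from R's RNG so set.seed() governs every draw.

#include <Rcpp.h>
using namespace Rcpp;

static const double PG_TRUNC = 0.64;         // Devroye proposal split point
static const int    PG_DEVROYE_MAX = 2;      // max integer shape for exact sums
static const double PG_NORMAL_MIN = 170.0;   // normal approximation above this

// ---- moments -------------------------------------------------------------

// E[PG(b,c)] = b/(2c) tanh(c/2); limit b/4 at c = 0
double pg_mean_scalar(double b, double c) {
  double ac = std::fabs(c);
  if (ac < 1e-6) return b * (0.25 - ac * ac / 48.0);
  return 0.5 * b / ac * std::tanh(0.5 * ac);
}

// Var[PG(b,c)] = b (sinh(c) - c) / (4 c^3 cosh^2(c/2)); limit b/24 at c = 0
double pg_var_scalar(double b, double c) {
  double ac = std::fabs(c);
  if (ac < 1e-3) return b / 24.0;
  double ch = std::cosh(0.5 * ac);
  return b * (std::sinh(ac) - ac) / (4.0 * ac * ac * ac * ch * ch);
}

// ---- Devroye sampler for PG(1, c) ----------------------------------------

// piecewise coefficients of the alternating series for the J*(1,z) density
static double pg_acoef(int n, double x) {
  double np = n + 0.5;
  if (x <= PG_TRUNC) {
    return M_PI * np * std::pow(2.0 / (M_PI * x), 1.5) *
           std::exp(-2.0 * np * np / x);
  }
  return M_PI * np * std::exp(-0.5 * np * np * M_PI * M_PI * x);
}

// inverse-Gaussian(mu = 1/z, lambda = 1) truncated to (0, PG_TRUNC)
static double pg_rtigauss(double z) {
  double t = PG_TRUNC;
  double X;
  if (z < 1.0 / t) { // mu > t: rejection from truncated inverse chi-square
    for (;;) {
      double E1, E2;
      do {
        E1 = exp_rand();
        E2 = exp_rand();
      } while (E1 * E1 > 2.0 * E2 / t);
      X = t / ((1.0 + t * E1) * (1.0 + t * E1));
      if (unif_rand() <= std::exp(-0.5 * z * z * X)) return X;
    }
  }
  double mu = 1.0 / z;
  for (;;) { // Michael-Schucany-Haas, repeat until below t
    double Y = norm_rand();
    Y *= Y;
    double muY = mu * Y;
    X = mu + 0.5 * mu * (muY - std::sqrt(4.0 * muY + muY * muY));
    if (unif_rand() > mu / (mu + X)) X = mu * mu / X;
    if (X < t) return X;
  }
}

static inline double pnorm_fast(double x) { // Phi(x) via erfc
  return 0.5 * std::erfc(-x * M_SQRT1_2);
}

// probability that the proposal comes from the exponential (right) piece
static double pg_mass_texpon(double z) {
  double t = PG_TRUNC;
  double fz = 0.125 * M_PI * M_PI + 0.5 * z * z;
  double b = std::sqrt(1.0 / t) * (t * z - 1.0);
  double a = -std::sqrt(1.0 / t) * (t * z + 1.0);
  double x0 = std::log(fz) + fz * t;
  if (x0 + z < 600.0) { // direct evaluation is safe from overflow
    double ex0 = std::exp(x0);
    double qdivp = 4.0 / M_PI *
        (ex0 * std::exp(-z) * pnorm_fast(b) + ex0 * std::exp(z) * pnorm_fast(a));
    return 1.0 / (1.0 + qdivp);
  }
  double xb = x0 - z + R::pnorm(b, 0.0, 1.0, 1, 1);
  double xa = x0 + z + R::pnorm(a, 0.0, 1.0, 1, 1);
  double qdivp = 4.0 / M_PI * (std::exp(xb) + std::exp(xa));
  return 1.0 / (1.0 + qdivp);
}

// exact draw of PG(1, c) (Devroye-type rejection; PG(1,c) = J*(1, c/2) / 4)
double rpg1_devroye(double c) {
  double z = std::fabs(c) * 0.5;
  double fz = 0.125 * M_PI * M_PI + 0.5 * z * z;
  double ratio = pg_mass_texpon(z);
  for (;;) {
    double X;
    if (unif_rand() < ratio)
      X = PG_TRUNC + exp_rand() / fz;
    else
      X = pg_rtigauss(z);
    double S = pg_acoef(0, X);
    double Y = unif_rand() * S;
    int n = 0;
    for (;;) {
      ++n;
      if (n % 2 == 1) {
        S -= pg_acoef(n, X);
        if (Y <= S) return 0.25 * X;
      } else {
        S += pg_acoef(n, X);
        if (Y > S) break;
      }
    }
  }
}

// ---- approximations ------------------------------------------------------

// two-moment gamma match (right-skewed like PG itself)
static double rpg_gamma_match(double b, double c) {
  double m = pg_mean_scalar(b, c), v = pg_var_scalar(b, c);
  double shape = m * m / v;
  return R::rgamma(shape, v / m); // scale = v/m
}

// single hybrid draw, any shape b > 0
double rpg_hybrid_scalar(double b, double c) {
  if (b > PG_NORMAL_MIN) {
    double m = pg_mean_scalar(b, c), s = std::sqrt(pg_var_scalar(b, c));
    double x = m + s * norm_rand();
    return x > 0.0 ? x : m; // PG support is positive; overflow essentially impossible
  }
  double out = 0.0;
  double bi = std::floor(b);
  double frac = b - bi;
  if (bi > PG_DEVROYE_MAX + 0.5) {
    return rpg_gamma_match(b, c);
  }
  for (int i = 0; i < (int)bi; ++i) out += rpg1_devroye(c);
  if (frac > 1e-12) out += rpg_gamma_match(frac, c);
  return out;
}

// truncated sum-of-gammas series with exact mean tail correction
double rpg_series_scalar(double b, double c, int nterms) {
  double c2 = c * c / (4.0 * M_PI * M_PI);
  double out = 0.0, partial = 0.0;
  for (int k = 1; k <= nterms; ++k) {
    double dk = (k - 0.5) * (k - 0.5) + c2;
    out += R::rgamma(b, 1.0) / dk;
    partial += 1.0 / dk;
  }
  double ac = std::fabs(c);
  double stot = (ac < 1e-8) ? 0.5 * M_PI * M_PI
                            : M_PI * M_PI * std::tanh(0.5 * ac) / ac;
  out += b * (stot - partial); // expected mass of the dropped tail
  return out / (2.0 * M_PI * M_PI);
}

// ---- exported vectorized interfaces --------------------------------------

// [[Rcpp::export(name = ".rpg_hybrid")]]
NumericVector rpg_hybrid_cpp(NumericVector b, NumericVector c) {
  R_xlen_t n = std::max(b.size(), c.size());
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    double bi = b[i % b.size()], ci = c[i % c.size()];
    if (!(bi > 0.0) || !R_finite(bi) || !R_finite(ci))
      stop("Polya-Gamma shape must be positive and finite");
    out[i] = rpg_hybrid_scalar(bi, ci);
  }
  return out;
}

// [[Rcpp::export(name = ".rpg_series")]]
NumericVector rpg_series_cpp(NumericVector b, NumericVector c, int nterms) {
  R_xlen_t n = std::max(b.size(), c.size());
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    double bi = b[i % b.size()], ci = c[i % c.size()];
    if (!(bi > 0.0) || !R_finite(bi) || !R_finite(ci))
      stop("Polya-Gamma shape must be positive and finite");
    out[i] = rpg_series_scalar(bi, ci, nterms);
  }
  return out;
}

// [[Rcpp::export(name = ".rpg_devroye")]]
NumericVector rpg_devroye_cpp(int n, double c) {
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rpg1_devroye(c);
  return out;
}

// [[Rcpp::export(name = ".pg_moments")]]
NumericMatrix pg_moments_cpp(NumericVector b, NumericVector c) {
  R_xlen_t n = std::max(b.size(), c.size());
  NumericMatrix out(n, 2);
  for (R_xlen_t i = 0; i < n; ++i) {
    out(i, 0) = pg_mean_scalar(b[i % b.size()], c[i % c.size()]);
    out(i, 1) = pg_var_scalar(b[i % b.size()], c[i % c.size()]);
  }
  return out;
}
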