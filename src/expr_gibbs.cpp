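// Gibbs sampler for the per-gene sparse expression model
//   x = Z gamma + eps,  eps ~ N(0, sigma2 I)
//   gamma_d ~ I_d delta0 + (1 - I_d) N(0, v2 sigma2),  I_d ~ Ber(pi)
//   pi ~ Unif(0,1); v2, sigma2 ~ inverse-gamma (a = b = 0 gives the Jeffreys limit)
//
// Indicator orientation: I_d = 1 selects the spike (gamma_d = 0).
// The indicator is drawn with gamma_d marginalized, then gamma_d is redrawn.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline double rinvgamma(double shape, double rate) {
  return 1.0 / R::rgamma(shape, 1.0 / rate);
}

static inline double clamp_pos(double x, double lo, double hi) {
  if (x < lo) return lo;
  if (x > hi) return hi;
  return x;
}

// [[Rcpp::export(name = ".expr_gibbs")]]
List expr_gibbs_cpp(const arma::vec& x, const arma::mat& Z,
                    int n_iter, int burn, int thin,
                    double fix_pi, double fix_v2, double fix_sigma2,
                    double a_v, double b_v, double a_sig, double b_sig) {
  const int n = Z.n_rows, g = Z.n_cols;
  arma::vec ztz(g);
  for (int d = 0; d < g; ++d) ztz[d] = arma::dot(Z.col(d), Z.col(d));

  // state
  arma::vec gamma(g, arma::fill::zeros);
  arma::uvec spike(g, arma::fill::ones); // I_d = 1: spike
  double pi = R_finite(fix_pi) ? fix_pi : 0.5;
  double v2 = R_finite(fix_v2) ? fix_v2 : 1.0;
  double sigma2 = R_finite(fix_sigma2) ? fix_sigma2 : arma::var(x);
  if (!(sigma2 > 0)) sigma2 = 1.0;
  arma::vec res = x; // residual x - Z gamma

  const int n_keep = (n_iter - burn) / thin;
  arma::mat gamma_draws(n_keep, g), spike_draws(n_keep, g);
  arma::vec sigma2_draws(n_keep), v2_draws(n_keep), pi_draws(n_keep);

  int kept = 0;
  for (int it = 0; it < n_iter; ++it) {
    // gamma_d and I_d, one coordinate at a time
    for (int d = 0; d < g; ++d) {
      if (spike[d] == 0) res += Z.col(d) * gamma[d];
      double z = arma::dot(Z.col(d), res) / sigma2;
      double P = ztz[d] / sigma2 + 1.0 / (v2 * sigma2);
      double logbf = -0.5 * std::log(v2 * sigma2 * P) + 0.5 * z * z / P;
      // logit of P(slab) = log((1-pi)/pi) + logBF(slab vs spike)
      double logit = std::log1p(-pi) - std::log(pi) + logbf;
      double pslab = 1.0 / (1.0 + std::exp(-logit));
      if (unif_rand() < pslab) {
        spike[d] = 0;
        gamma[d] = z / P + norm_rand() / std::sqrt(P);
        res -= Z.col(d) * gamma[d];
      } else {
        spike[d] = 1;
        gamma[d] = 0.0;
      }
    }
    int nspike = arma::accu(spike), nslab = g - nspike;
    double ss_slab = 0.0;
    for (int d = 0; d < g; ++d) ss_slab += gamma[d] * gamma[d];

    if (!R_finite(fix_pi))
      pi = R::rbeta(1.0 + nspike, 1.0 + nslab);
    if (!R_finite(fix_v2)) {
      if (nslab > 0)
        v2 = rinvgamma(a_v + 0.5 * nslab, b_v + 0.5 * ss_slab / sigma2);
      else if (a_v > 0 && b_v > 0)
        v2 = rinvgamma(a_v, b_v);
      // Jeffreys with no slab coordinates: conditional degenerate, retain v2
      v2 = clamp_pos(v2, 1e-10, 1e10);
    }
    if (!R_finite(fix_sigma2)) {
      double ssr = arma::dot(res, res);
      sigma2 = rinvgamma(a_sig + 0.5 * n + 0.5 * nslab,
                         b_sig + 0.5 * ssr + 0.5 * ss_slab / v2);
      sigma2 = clamp_pos(sigma2, 1e-10, 1e10);
    }

    if (it >= burn && (it - burn) % thin == 0 && kept < n_keep) {
      gamma_draws.row(kept) = gamma.t();
      for (int d = 0; d < g; ++d) spike_draws(kept, d) = spike[d];
      sigma2_draws[kept] = sigma2;
      v2_draws[kept] = v2;
      pi_draws[kept] = pi;
      ++kept;
    }
  }

  return List::create(
      _["gamma"] = gamma_draws, _["spike"] = spike_draws,
      _["sigma2"] = sigma2_draws, _["v2"] = v2_draws, _["pi"] = pi_draws);
}
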