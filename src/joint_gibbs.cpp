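// Gibbs sampler for the joint gene/factor fine-mapping model in one region.
//
//   f_l  = sum_j beta_jl xhat_j + eps_l,          eps_l ~ N(0, omega2_l I)
//   ytil_ik = lambda_k' F_i + e_ik                (precision 1/tau2_k continuous,
//                                                  psi_ik for augmented discrete)
//   beta_jl = I_j U_jl b_jl,  b_jl ~ N(0, s2 omega2_l),
//   I_j ~ Ber(pi1), U_jl ~ Ber(pi2), pi1, pi2 ~ Unif(0,1)
//   lambda_kl ~ N(0, 1/(phi_kl eta_l)), phi_kl ~ Ga(3/2, 3/2),
//   eta_l = prod_{r<=l} theta_r, theta_1 ~ Ga(a1,1), theta_h ~ Ga(a2,1)
//   binary:  y ~ Ber(logit^-1(lambda'F));  count: y ~ NB(r_k, logit^-1(lambda'F))
//
// Indicators are drawn with b marginalized (collapsed odds), then b is redrawn,
// so (I, b) and (U, b) move as blocks. The NB dispersion r_k is drawn with psi
// marginalized via latent CRT counts, then psi is redrawn: a valid partially
// collapsed block. Adaptive truncation runs only during burn-in so stored
// draws share one m.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

double rpg_hybrid_scalar(double b, double c);
double rpg1_devroye(double c);

static inline double rinvgamma(double shape, double rate) {
  return 1.0 / R::rgamma(shape, 1.0 / rate);
}
static inline double clamp_pos(double x) {
  if (x < 1e-10) return 1e-10;
  if (x > 1e10) return 1e10;
  return x;
}
static inline double softplus(double x) {
  if (x > 30.0) return x;
  if (x < -30.0) return std::exp(x);
  return std::log1p(std::exp(x));
}
static inline double sigmoid(double x) {
  return 1.0 / (1.0 + std::exp(-x));
}

// Chinese-restaurant-table draw: number of tables from y customers, rate r
static inline int rcrt(int y, double r) {
  int l = 0;
  for (int t = 1; t <= y; ++t)
    if (unif_rand() < r / (r + t - 1.0)) ++l;
  return l;
}

// [[Rcpp::export(name = ".joint_gibbs")]]
List joint_gibbs_cpp(const arma::mat& X, const arma::mat& Y,
                     const IntegerVector& ytype, List init, List cfg) {
  const int n = Y.n_rows, q = Y.n_cols, p = X.n_cols;

  // --- config ---
  const int n_iter = cfg["n_iter"], burn = cfg["burn"], thin = cfg["thin"];
  const bool adapt = cfg["adapt"];
  const double alpha0 = cfg["alpha0"], alpha1 = cfg["alpha1"];
  const double adapt_eps = cfg["adapt_eps"];
  const int m_max = cfg["m_max"];
  const double a1 = cfg["a1"], a2 = cfg["a2"];
  const double as2 = cfg["as2"], bs2 = cfg["bs2"];
  const double aw = cfg["aw"], bw = cfg["bw"];
  const double atau = cfg["atau"], btau = cfg["btau"];
  const double ar = cfg["ar"], br = cfg["br"];
  const bool fix_r = cfg["fix_r"];
  const bool up_lambda = cfg["up_lambda"], up_F = cfg["up_F"];
  const bool up_s2 = cfg["up_s2"], up_omega2 = cfg["up_omega2"];
  const bool up_pi1 = cfg["up_pi1"], up_pi2 = cfg["up_pi2"];
  const bool up_tau2 = cfg["up_tau2"];
  const bool up_I = cfg["up_I"], up_U = cfg["up_U"];

  // --- state ---
  arma::ivec I = as<arma::ivec>(init["I"]);
  arma::mat U = as<arma::mat>(init["U"]);
  arma::mat b = as<arma::mat>(init["b"]);
  double pi1 = init["pi1"], pi2 = init["pi2"], s2 = init["s2"];
  arma::vec omega2 = as<arma::vec>(init["omega2"]);
  arma::mat Lambda = as<arma::mat>(init["Lambda"]);
  arma::mat F = as<arma::mat>(init["F"]);
  arma::mat phi = as<arma::mat>(init["phi"]);
  arma::vec theta = as<arma::vec>(init["theta"]);
  arma::vec tau2 = as<arma::vec>(init["tau2"]);
  arma::vec rdisp = as<arma::vec>(init["r"]);
  int m = Lambda.n_cols;

  arma::vec eta(m);
  {
    double cum = 1.0;
    for (int l = 0; l < m; ++l) { cum *= theta[l]; eta[l] = cum; }
  }
  arma::mat B = b % U;
  for (int j = 0; j < p; ++j) if (I[j] == 0) B.row(j).zeros();

  arma::vec xtx(p);
  for (int j = 0; j < p; ++j) xtx[j] = arma::dot(X.col(j), X.col(j));

  const int n_keep = (n_iter - burn + thin - 1) / thin;
  // storage allocated on first kept sweep (m is frozen after burn-in)
  arma::cube B_draws, U_draws, L_draws;
  arma::imat I_draws;
  arma::mat om_draws, tau_draws, r_draws;
  arma::vec s2_draws(n_keep), pi1_draws(n_keep), pi2_draws(n_keep);
  arma::ivec m_traj(n_iter);
  arma::mat Fmean;
  arma::mat Lambda_ref; // last burn-in Lambda, alignment reference
  int kept = 0;

  arma::mat W(n, q), Ytil(n, q), M(n, q);

  for (int it = 0; it < n_iter; ++it) {
    // linear predictor with current F, Lambda
    M = F * Lambda.t();

    // --- r_k (count columns): CRT, psi marginalized ---
    if (!fix_r) {
      for (int k = 0; k < q; ++k) {
        if (ytype[k] != 2) continue;
        int lsum = 0;
        double rate = br;
        for (int i = 0; i < n; ++i) {
          lsum += rcrt((int)Y(i, k), rdisp[k]);
          rate += softplus(M(i, k));
        }
        double rk = R::rgamma(ar + lsum, 1.0 / rate);
        if (rk < 1e-3) rk = 1e-3;
        if (rk > 1e4) rk = 1e4;
        rdisp[k] = rk;
      }
    }

    // --- psi | xi, linear predictor; transformed response and weights ---
    for (int k = 0; k < q; ++k) {
      if (ytype[k] == 0) {
        double wk = 1.0 / tau2[k];
        for (int i = 0; i < n; ++i) { W(i, k) = wk; Ytil(i, k) = Y(i, k); }
      } else if (ytype[k] == 1) {
        for (int i = 0; i < n; ++i) {
          double psi = std::max(rpg1_devroye(M(i, k)), 1e-9);
          W(i, k) = psi;
          Ytil(i, k) = (Y(i, k) - 0.5) / psi;
        }
      } else {
        double rk = rdisp[k];
        for (int i = 0; i < n; ++i) {
          double xi = Y(i, k) + rk;
          double psi = std::max(rpg_hybrid_scalar(xi, M(i, k)), 1e-9);
          W(i, k) = psi;
          Ytil(i, k) = (Y(i, k) - 0.5 * xi) / psi;
        }
      }
    }

    // --- F rows ---
    if (up_F) {
      arma::mat Mu = X * B; // prior means
      // constant part of the likelihood precision (continuous columns)
      // plus the prior precision; per-row discrete terms added below
      arma::mat Abase(m, m, arma::fill::zeros);
      std::vector<int> disc;
      for (int k = 0; k < q; ++k) {
        if (ytype[k] == 0) {
          double wk = 1.0 / tau2[k];
          for (int a = 0; a < m; ++a)
            for (int c = 0; c < m; ++c)
              Abase(a, c) += wk * Lambda(k, a) * Lambda(k, c);
        } else {
          disc.push_back(k);
        }
      }
      for (int l = 0; l < m; ++l) Abase(l, l) += 1.0 / omega2[l];
      const int nd = (int)disc.size();
      // outer products lambda_k lambda_k' of the discrete rows, flattened
      arma::mat Odisc(m * m, nd);
      for (int d = 0; d < nd; ++d) {
        int k = disc[d];
        for (int a = 0; a < m; ++a)
          for (int c = 0; c < m; ++c)
            Odisc(a * m + c, d) = Lambda(k, a) * Lambda(k, c);
      }
      arma::mat Pbuf(m, m);
      arma::vec rhs(m), mu(m), zdraw(m);
      for (int i = 0; i < n; ++i) {
        Pbuf = Abase;
        double* Pp = Pbuf.memptr();
        for (int l = 0; l < m; ++l) rhs[l] = Mu(i, l) / omega2[l];
        for (int d = 0; d < nd; ++d) {
          int k = disc[d];
          const double wik = W(i, k);
          const double* Op = Odisc.colptr(d);
          for (int a = 0; a < m * m; ++a) Pp[a] += wik * Op[a];
        }
        for (int k = 0; k < q; ++k) {
          double wy = W(i, k) * Ytil(i, k);
          for (int l = 0; l < m; ++l) rhs[l] += wy * Lambda(k, l);
        }
        // in-place lower Cholesky of Pbuf
        for (int a = 0; a < m; ++a) {
          for (int c = 0; c <= a; ++c) {
            double s = Pbuf(a, c);
            for (int kk = 0; kk < c; ++kk) s -= Pbuf(a, kk) * Pbuf(c, kk);
            if (a == c) {
              if (s <= 0) stop("F update: non-positive-definite precision");
              Pbuf(a, a) = std::sqrt(s);
            } else {
              Pbuf(a, c) = s / Pbuf(c, c);
            }
          }
        }
        // mu = P^{-1} rhs via forward/back substitution
        for (int a = 0; a < m; ++a) {
          double s = rhs[a];
          for (int kk = 0; kk < a; ++kk) s -= Pbuf(a, kk) * mu[kk];
          mu[a] = s / Pbuf(a, a);
        }
        for (int a = m - 1; a >= 0; --a) {
          double s = mu[a];
          for (int kk = a + 1; kk < m; ++kk) s -= Pbuf(kk, a) * mu[kk];
          mu[a] = s / Pbuf(a, a);
        }
        // draw: mu + L^{-T} z
        for (int l = 0; l < m; ++l) zdraw[l] = norm_rand();
        for (int a = m - 1; a >= 0; --a) {
          double s = zdraw[a];
          for (int kk = a + 1; kk < m; ++kk) s -= Pbuf(kk, a) * zdraw[kk];
          zdraw[a] = s / Pbuf(a, a);
        }
        for (int l = 0; l < m; ++l) F(i, l) = mu[l] + zdraw[l];
      }
    }

    // --- Lambda rows, local scales phi, gamma-process increments theta ---
    if (up_lambda) {
      for (int k = 0; k < q; ++k) {
        arma::vec wk = W.col(k);
        arma::mat P = F.t() * (F.each_col() % wk);
        P = 0.5 * (P + P.t()); // enforce exact symmetry for chol
        P.diag() += phi.row(k).t() % eta;
        arma::vec rhs = F.t() * (wk % Ytil.col(k));
        if (!P.is_finite() || !rhs.is_finite())
          stop("loading update: non-finite precision (phenotype %d)", k + 1);
        arma::mat Lc = arma::chol(P, "lower");
        arma::vec mu = arma::solve(arma::trimatu(Lc.t()),
                                   arma::solve(arma::trimatl(Lc), rhs));
        arma::vec zdraw(m);
        for (int l = 0; l < m; ++l) zdraw[l] = norm_rand();
        Lambda.row(k) = (mu + arma::solve(arma::trimatu(Lc.t()), zdraw)).t();
      }
      for (int k = 0; k < q; ++k)
        for (int l = 0; l < m; ++l)
          phi(k, l) = R::rgamma(2.0, 1.0 / (1.5 + 0.5 * eta[l] *
                                            Lambda(k, l) * Lambda(k, l)));
      // column sums of phi * lambda^2
      arma::vec colss(m);
      for (int l = 0; l < m; ++l)
        colss[l] = arma::dot(phi.col(l), arma::square(Lambda.col(l)));
      for (int h = 0; h < m; ++h) {
        double shape = (h == 0 ? a1 : a2) + 0.5 * q * (m - h);
        double rate = 1.0;
        double cum = 1.0;
        for (int l = 0; l < m; ++l) {
          if (l != h) cum *= theta[l];
          if (l >= h) rate += 0.5 * cum * colss[l];
        }
        theta[h] = R::rgamma(shape, 1.0 / rate);
        if (theta[h] < 1e-8) theta[h] = 1e-8;
      }
      double cum = 1.0;
      for (int l = 0; l < m; ++l) { cum *= theta[l]; eta[l] = cum; }
    }

    // --- tau2 (continuous columns) ---
    if (up_tau2) {
      for (int k = 0; k < q; ++k) {
        if (ytype[k] != 0) continue;
        arma::vec resid = Y.col(k) - F * Lambda.row(k).t();
        tau2[k] = clamp_pos(rinvgamma(atau + 0.5 * n,
                                      btau + 0.5 * arma::dot(resid, resid)));
      }
    }

    // --- gene effects: (I_j, U_jl, b_jl) with collapsed indicator odds ---
    arma::mat R = F - X * B;
    double log_pi1 = std::log(pi1) - std::log1p(-pi1);
    double log_pi2 = std::log(pi2) - std::log1p(-pi2);
    for (int j = 0; j < p; ++j) {
      for (int l = 0; l < m; ++l)
        if (B(j, l) != 0.0) R.col(l) += X.col(j) * B(j, l);
      arma::vec zl(m), Pl(m), logbf(m);
      for (int l = 0; l < m; ++l) {
        zl[l] = arma::dot(X.col(j), R.col(l)) / omega2[l];
        Pl[l] = xtx[j] / omega2[l] + 1.0 / (s2 * omega2[l]);
        logbf[l] = -0.5 * std::log(s2 * omega2[l] * Pl[l]) +
                   0.5 * zl[l] * zl[l] / Pl[l];
      }
      if (up_I) {
        double logit = log_pi1;
        for (int l = 0; l < m; ++l)
          if (U(j, l) > 0.5) logit += logbf[l];
        I[j] = (unif_rand() < sigmoid(logit)) ? 1 : 0;
      }
      for (int l = 0; l < m; ++l) {
        if (up_U) {
          double logit = log_pi2 + (I[j] == 1 ? logbf[l] : 0.0);
          U(j, l) = (unif_rand() < sigmoid(logit)) ? 1.0 : 0.0;
        }
        if (I[j] == 1 && U(j, l) > 0.5) {
          b(j, l) = zl[l] / Pl[l] + norm_rand() / std::sqrt(Pl[l]);
          B(j, l) = b(j, l);
          R.col(l) -= X.col(j) * B(j, l);
        } else {
          b(j, l) = norm_rand() * std::sqrt(s2 * omega2[l]);
          B(j, l) = 0.0;
        }
      }
    }

    // --- inclusion probabilities, scales ---
    if (up_pi1) {
      int si = arma::accu(I);
      pi1 = R::rbeta(1.0 + si, 1.0 + p - si);
    }
    if (up_pi2) {
      double su = arma::accu(U);
      pi2 = R::rbeta(1.0 + su, 1.0 + p * m - su);
    }
    if (up_s2) {
      double ss = 0.0;
      for (int l = 0; l < m; ++l)
        ss += arma::dot(b.col(l), b.col(l)) / omega2[l];
      s2 = clamp_pos(rinvgamma(as2 + 0.5 * p * m, bs2 + 0.5 * ss));
    }
    if (up_omega2) {
      for (int l = 0; l < m; ++l) {
        double ssr = arma::dot(R.col(l), R.col(l));
        double ssb = arma::dot(b.col(l), b.col(l));
        omega2[l] = clamp_pos(rinvgamma(aw + 0.5 * (n + p),
                                        bw + 0.5 * ssr + 0.5 * ssb / s2));
      }
    }

    // --- adaptive truncation (burn-in only) ---
    if (adapt && it < burn && m_max >= 1 &&
        unif_rand() < std::exp(-alpha0 - alpha1 * (double)(it + 1))) {
      arma::uvec small(m, arma::fill::zeros);
      int nsmall = 0;
      for (int l = 0; l < m; ++l) {
        if (arma::abs(Lambda.col(l)).max() < adapt_eps) { small[l] = 1; ++nsmall; }
      }
      if (nsmall > 0) {
        if (nsmall == m) { // keep the least-shrunk column: m >= 1 floor
          arma::vec mx(m);
          for (int l = 0; l < m; ++l) mx[l] = arma::abs(Lambda.col(l)).max();
          small[mx.index_max()] = 0;
          nsmall = m - 1;
        }
        for (int l = m - 1; l >= 0; --l) {
          if (!small[l]) continue;
          Lambda.shed_col(l); phi.shed_col(l); U.shed_col(l); b.shed_col(l);
          B.shed_col(l); F.shed_col(l);
          omega2.shed_row(l); theta.shed_row(l);
        }
        m -= nsmall;
      } else if (m < m_max) {
        double th_new = R::rgamma(m == 0 ? a1 : a2, 1.0);
        theta.resize(m + 1); theta[m] = std::max(th_new, 1e-8);
        double eta_new = (m == 0 ? 1.0 : eta[m - 1]) * theta[m];
        arma::vec phinew(q), lamnew(q);
        for (int k = 0; k < q; ++k) {
          phinew[k] = R::rgamma(1.5, 1.0 / 1.5);
          lamnew[k] = norm_rand() / std::sqrt(phinew[k] * eta_new);
        }
        Lambda.insert_cols(m, lamnew);
        phi.insert_cols(m, phinew);
        double om_new = arma::mean(omega2);
        omega2.resize(m + 1); omega2[m] = om_new;
        arma::vec bnew(p), Unew(p), Bnew(p);
        for (int j = 0; j < p; ++j) {
          Unew[j] = (unif_rand() < pi2) ? 1.0 : 0.0;
          bnew[j] = norm_rand() * std::sqrt(s2 * om_new);
          Bnew[j] = (I[j] == 1 && Unew[j] > 0.5) ? bnew[j] : 0.0;
        }
        U.insert_cols(m, Unew);
        b.insert_cols(m, bnew);
        B.insert_cols(m, Bnew);
        arma::vec fnew = X * Bnew;
        for (int i = 0; i < n; ++i) fnew[i] += norm_rand() * std::sqrt(om_new);
        F.insert_cols(m, fnew);
        ++m;
      }
      double cum = 1.0;
      eta.set_size(m);
      for (int l = 0; l < m; ++l) { cum *= theta[l]; eta[l] = cum; }
    }

    m_traj[it] = m;
    if (it == burn - 1 || (burn == 0 && it == 0 && kept == 0)) Lambda_ref = Lambda;

    if (it >= burn && (it - burn) % thin == 0 && kept < n_keep) {
      if (kept == 0) {
        B_draws.set_size(p, m, n_keep);
        U_draws.set_size(p, m, n_keep);
        L_draws.set_size(q, m, n_keep);
        I_draws.set_size(n_keep, p);
        om_draws.set_size(n_keep, m);
        tau_draws.set_size(n_keep, q);
        r_draws.set_size(n_keep, q);
        Fmean.zeros(n, m);
        if (Lambda_ref.n_elem == 0) Lambda_ref = Lambda;
      }
      B_draws.slice(kept) = B;
      U_draws.slice(kept) = U;
      L_draws.slice(kept) = Lambda;
      for (int j = 0; j < p; ++j) I_draws(kept, j) = I[j];
      om_draws.row(kept) = omega2.t();
      tau_draws.row(kept) = tau2.t();
      r_draws.row(kept) = rdisp.t();
      s2_draws[kept] = s2;
      pi1_draws[kept] = pi1;
      pi2_draws[kept] = pi2;
      Fmean += F;
      ++kept;
    }
  }
  if (kept > 0) Fmean /= (double)kept;

  List final_state = List::create(
      _["I"] = IntegerVector(I.begin(), I.end()), _["U"] = U, _["b"] = b,
      _["pi1"] = pi1, _["pi2"] = pi2, _["s2"] = s2, _["omega2"] = omega2,
      _["Lambda"] = Lambda, _["F"] = F, _["phi"] = phi, _["theta"] = theta,
      _["tau2"] = tau2, _["r"] = rdisp, _["m"] = m);

  return List::create(
      _["B"] = B_draws, _["U"] = U_draws, _["I"] = I_draws,
      _["Lambda"] = L_draws, _["omega2"] = om_draws, _["tau2"] = tau_draws,
      _["r"] = r_draws, _["s2"] = s2_draws, _["pi1"] = pi1_draws,
      _["pi2"] = pi2_draws, _["m_traj"] = m_traj, _["Fmean"] = Fmean,
      _["Lambda_ref"] = Lambda_ref, _["state"] = final_state,
      _["n_kept"] = kept);
}
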