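# Geweke-style simulation-consistency harness: forward prior/data draws vs
# alternating Gibbs sweeps and data re-simulation. Proper inverse-gamma
# hyperparameters are required (improper Jeffreys limits cannot be
# forward-sampled). Tracked statistics are bounded (tanh of effects and
# loadings, indicators) so heavy prior tails do not mask disagreement.

geweke_hyper <- function() {
  list(prior_s2 = c(4, 3), prior_omega2 = c(4, 3), prior_tau2 = c(4, 3),
       prior_r = c(2, 2), a1 = 3, a2 = 3)
}

geweke_forward_draw <- function(X, types, m, hy) {
  n <- nrow(X); p <- ncol(X); q <- length(types)
  rinvg <- function(k, sh, rt) 1 / rgamma(k, sh, rate = rt)
  pi1 <- runif(1); pi2 <- runif(1)
  s2 <- rinvg(1, hy$prior_s2[1], hy$prior_s2[2])
  omega2 <- rinvg(m, hy$prior_omega2[1], hy$prior_omega2[2])
  I <- rbinom(p, 1, pi1)
  U <- matrix(rbinom(p * m, 1, pi2), p, m)
  b <- matrix(rnorm(p * m, 0, rep(sqrt(s2 * omega2), each = p)), p, m)
  B <- b * U * I
  Fmat <- X %*% B + matrix(rnorm(n * m, 0, rep(sqrt(omega2), each = n)), n, m)
  theta <- c(rgamma(1, hy$a1, 1), if (m > 1) rgamma(m - 1, hy$a2, 1))
  eta <- cumprod(theta)
  phi <- matrix(rgamma(q * m, 1.5, rate = 1.5), q, m)
  Lambda <- matrix(rnorm(q * m, 0, sqrt(1 / (phi * rep(eta, each = q)))), q, m)
  tau2 <- rinvg(q, hy$prior_tau2[1], hy$prior_tau2[2])
  r <- rgamma(q, hy$prior_r[1], rate = hy$prior_r[2])
  list(I = as.integer(I), U = U, b = b, pi1 = pi1, pi2 = pi2, s2 = s2,
       omega2 = omega2, Lambda = Lambda, F = Fmat, phi = phi, theta = theta,
       tau2 = tau2, r = r)
}

geweke_simulate_Y <- function(state, types) {
  pred <- state$F %*% t(state$Lambda)
  n <- nrow(pred); q <- length(types)
  Y <- matrix(0, n, q)
  for (k in seq_len(q)) {
    Y[, k] <- switch(types[k],
      continuous = rnorm(n, pred[, k], sqrt(state$tau2[k])),
      binary = rbinom(n, 1, plogis(pred[, k])),
      count = rnbinom(n, size = state$r[k],
                      mu = state$r[k] * pmin(exp(pred[, k]), 1e4)))
  }
  Y
}

geweke_track <- function(state) {
  B <- state$b * state$U * (state$I == 1)
  c(tB11 = tanh(B[1, 1]), tB22 = tanh(B[2, 2]), I1 = state$I[1],
    U11 = state$U[1, 1], tL11 = tanh(state$Lambda[1, 1]),
    tL21 = tanh(state$Lambda[2, 1]), tL32 = tanh(state$Lambda[3, 2]),
    tL12 = tanh(state$Lambda[1, 2]))
}

run_geweke <- function(n = 30, p = 2, q = 3, m = 2, n_forward = 30000,
                       n_succ = 60000, thin = 3, seed = 1,
                       types = c("continuous", "binary", "count")) {
  set.seed(seed)
  X <- std_matrix(n, p)
  hy <- geweke_hyper()
  cfg <- chain_config(iterations = 2, burnin = 1, thin = 1, m_init = m,
                      m_max = m, adapt = FALSE, a1 = hy$a1, a2 = hy$a2,
                      prior_s2 = hy$prior_s2, prior_omega2 = hy$prior_omega2,
                      prior_tau2 = hy$prior_tau2, prior_r = hy$prior_r)
  fw <- matrix(0, n_forward, 8)
  for (i in seq_len(n_forward))
    fw[i, ] <- geweke_track(geweke_forward_draw(X, types, m, hy))
  st <- geweke_forward_draw(X, types, m, hy)
  nk <- n_succ %/% thin
  sc <- matrix(0, nk, 8)
  for (i in seq_len(n_succ)) {
    Y <- geweke_simulate_Y(st, types)
    st <- gibbs_sweep(st, X, Y, types, cfg)
    if (i %% thin == 0) sc[i %/% thin, ] <- geweke_track(st)
  }
  colnames(fw) <- colnames(sc) <- names(geweke_track(st))
  batch_se <- function(v, nb = 40) {
    idx <- rep(seq_len(nb), each = ceiling(length(v) / nb))[seq_along(v)]
    bm <- tapply(v, idx, mean)
    sd(bm) / sqrt(nb)
  }
  zs <- function(f) (colMeans(f(fw)) - colMeans(f(sc))) /
    sqrt(apply(f(fw), 2, var) / n_forward + apply(f(sc), 2, batch_se)^2)
  list(z_mean = zs(identity), z_second = zs(function(x) x^2))
}
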