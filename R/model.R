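#' Chain and prior configuration for the joint fine-mapping sampler
#'
#' @param iterations,burnin,thin Gibbs chain controls. Adaptation of the
#'   factor truncation runs only during burn-in so stored draws share one
#'   truncation level.
#' @param m_init,m_max initial and maximal factor truncation; defaults
#'   `min(q, 15)` and `q`, resolved at run time.
#' @param a1,a2 gamma-process shrinkage hyperparameters (> 1); larger values
#'   shrink higher-indexed factor loadings more aggressively.
#' @param alpha0,alpha1 adaptation probability `exp(-alpha0 - alpha1 t)` at
#'   sweep `t`.
#' @param adapt_eps loading magnitude below which a factor column counts as
#'   negligible.
#' @param adapt enable the adaptive truncation step.
#' @param prior_s2,prior_omega2,prior_tau2 `c(shape, rate)` inverse-gamma
#'   hyperparameters; `c(0, 0)` is the Jeffreys limit.
#' @param prior_r `c(shape, rate)` gamma prior on negative-binomial
#'   dispersions.
#' @param fix_r freeze the dispersion parameters at their initial values.
#' @param fixed named list freezing blocks at supplied values, for oracle
#'   validation: entries among `Lambda` (also freezes its `phi`/`theta`
#'   scales), `F`, `s2`, `omega2`, `pi1`, `pi2`, `tau2`, `I`, `U`, `r`.
#'   `I`/`U` set to matrices/vectors of ones force all indicators on.
#' @return a `phenofm_chain_config` list.
#' @export
chain_config <- function(iterations = 10000, burnin = 5000, thin = 5,
                         m_init = NULL, m_max = NULL, a1 = 3, a2 = 3,
                         alpha0 = 1, alpha1 = 5e-4, adapt_eps = 1e-2,
                         adapt = TRUE, prior_s2 = c(0, 0),
                         prior_omega2 = c(0, 0), prior_tau2 = c(0, 0),
                         prior_r = c(1, 0.01), fix_r = FALSE, fixed = list()) {
  .assert(iterations > burnin && burnin >= 0 && thin >= 1, "invalid chain lengths")
  .assert(a1 > 1 && a2 > 1, "shrinkage hyperparameters a1, a2 must exceed 1")
  .assert((iterations - burnin) / thin >= 1, "no draws would be stored")
  bad <- setdiff(names(fixed), c("Lambda", "F", "s2", "omega2", "pi1", "pi2",
                                 "tau2", "I", "U", "r"))
  .assert(length(bad) == 0, paste("unknown fixed blocks:", paste(bad, collapse = ", ")))
  structure(list(iterations = as.integer(iterations),
                 burnin = as.integer(burnin), thin = as.integer(thin),
                 m_init = m_init, m_max = m_max, a1 = a1, a2 = a2,
                 alpha0 = alpha0, alpha1 = alpha1, adapt_eps = adapt_eps,
                 adapt = isTRUE(adapt), prior_s2 = prior_s2,
                 prior_omega2 = prior_omega2, prior_tau2 = prior_tau2,
                 prior_r = prior_r, fix_r = isTRUE(fix_r), fixed = fixed),
            class = "phenofm_chain_config")
}

.type_codes <- function(types) {
  .assert(all(types %in% c("continuous", "binary", "count")),
          "types must be continuous/binary/count")
  c(continuous = 0L, binary = 1L, count = 2L)[types]
}

# moment estimate of a negative-binomial dispersion, clamped to a sane range
.init_r <- function(y) {
  mu <- mean(y); v <- var(y)
  r <- if (v > mu) mu^2 / (v - mu) else 10
  min(max(r, 0.5), 50)
}

# initial pseudo-data at prior-mean Polya-Gamma weights (c = 0)
.init_ytilde <- function(Y, types, r0) {
  out <- Y
  for (k in seq_len(ncol(Y))) {
    if (types[k] == "continuous") out[, k] <- Y[, k] - mean(Y[, k])
    else if (types[k] == "binary") out[, k] <- 4 * (Y[, k] - 0.5)
    else {
      xi <- Y[, k] + r0[k]
      out[, k] <- (Y[, k] - 0.5 * xi) / (xi / 4)
    }
  }
  out
}

# warm start: truncated SVD of the initial pseudo-data, ridge for b
.init_state <- function(X, Y, types, m0, config) {
  n <- nrow(Y); q <- ncol(Y); p <- ncol(X)
  r0 <- vapply(seq_len(q), function(k)
    if (types[k] == "count") .init_r(Y[, k]) else 1, numeric(1))
  Yt <- .init_ytilde(Y, types, r0)
  sv <- svd(Yt, nu = m0, nv = m0)
  d <- pmax(sv$d[seq_len(m0)], 1e-3)
  Fmat <- sqrt(n) * sv$u
  Lambda <- sv$v %*% diag(d / sqrt(n), m0)
  XtX <- crossprod(X)
  b <- solve(XtX + diag(p), crossprod(X, Fmat))
  resid <- Fmat - X %*% b
  omega2 <- pmax(apply(resid, 2, var), 0.05)
  tau2 <- rep(1, q)
  for (k in seq_len(q)) {
    if (types[k] == "continuous") {
      rk <- Y[, k] - Fmat %*% Lambda[k, ]
      tau2[k] <- max(var(as.vector(rk)), 0.05)
    }
  }
  # genes start excluded (the empty model); the collapsed Bernoulli updates
  # switch a gene on in one sweep when its Bayes factor warrants it, whereas
  # starting all-on lets early factor updates align with GReX directions and
  # can lock spurious inclusions in under null data
  list(I = rep(0L, p), U = matrix(1, p, m0), b = b, pi1 = 0.5, pi2 = 0.5,
       s2 = 1, omega2 = omega2, Lambda = Lambda, F = Fmat,
       phi = matrix(1, q, m0), theta = rep(1, m0), tau2 = tau2, r = r0)
}

# apply a config's `fixed` blocks onto an init state; returns updated state
# plus the C++ update flags
.apply_fixed <- function(state, config, p, q, m0) {
  fx <- config$fixed
  flags <- list(up_lambda = TRUE, up_F = TRUE, up_s2 = TRUE, up_omega2 = TRUE,
                up_pi1 = TRUE, up_pi2 = TRUE, up_tau2 = TRUE, up_I = TRUE,
                up_U = TRUE, fix_r = config$fix_r)
  if (!is.null(fx$Lambda)) {
    .assert(all(dim(fx$Lambda) == c(q, m0)), "fixed Lambda has wrong shape")
    state$Lambda <- fx$Lambda; flags$up_lambda <- FALSE
  }
  if (!is.null(fx$F)) {
    state$F <- fx$F; flags$up_F <- FALSE
  }
  if (!is.null(fx$s2)) { state$s2 <- fx$s2; flags$up_s2 <- FALSE }
  if (!is.null(fx$omega2)) {
    state$omega2 <- rep_len(fx$omega2, m0); flags$up_omega2 <- FALSE
  }
  if (!is.null(fx$pi1)) { state$pi1 <- fx$pi1; flags$up_pi1 <- FALSE }
  if (!is.null(fx$pi2)) { state$pi2 <- fx$pi2; flags$up_pi2 <- FALSE }
  if (!is.null(fx$tau2)) {
    state$tau2 <- rep_len(fx$tau2, q); flags$up_tau2 <- FALSE
  }
  if (!is.null(fx$I)) { state$I <- rep_len(as.integer(fx$I), p); flags$up_I <- FALSE }
  if (!is.null(fx$U)) {
    state$U <- matrix(rep_len(as.numeric(fx$U), p * m0), p, m0)
    flags$up_U <- FALSE
  }
  if (!is.null(fx$r)) { state$r <- rep_len(fx$r, q); flags$fix_r <- TRUE }
  list(state = state, flags = flags)
}

.cpp_cfg <- function(config, flags, m_max, n_iter, burn, adapt) {
  c(list(n_iter = as.integer(n_iter), burn = as.integer(burn),
         thin = as.integer(config$thin), adapt = adapt,
         alpha0 = config$alpha0, alpha1 = config$alpha1,
         adapt_eps = config$adapt_eps, m_max = as.integer(m_max),
         a1 = config$a1, a2 = config$a2,
         as2 = config$prior_s2[1], bs2 = config$prior_s2[2],
         aw = config$prior_omega2[1], bw = config$prior_omega2[2],
         atau = config$prior_tau2[1], btau = config$prior_tau2[2],
         ar = config$prior_r[1], br = config$prior_r[2]),
    flags)
}

#' Run the joint Gibbs sampler over one genomic region
#'
#' Fits the supervised sparse factor model linking the region's GReX to
#' latent phenotype factors: gene effects carry two-level indicator
#' (spike-and-slab) priors giving exact posterior sparsity, loadings carry a
#' multiplicative gamma-process shrinkage prior with an adaptive truncation
#' step, and binary/count phenotypes enter through Polya-Gamma augmentation.
#' Initialization is a truncated-SVD warm start. Optional covariates are
#' residualized out of GReX and continuous phenotype columns (discrete
#' columns are left untouched; a message notes this).
#'
#' @param grex standardized `n2 x p` GReX matrix for one region (gene ids as
#'   column names).
#' @param Y `n2 x q` phenotype matrix, complete (no missing entries).
#' @param types per-column outcome types (`"continuous"|"binary"|"count"`).
#' @param config a [chain_config()].
#' @param covariates optional numeric covariate matrix.
#' @param seed integer seed; two runs with identical inputs and seed are
#'   identical.
#' @return a `phenofm_draws` object with stored thinned draws (`B`, `I`,
#'   `U`, `Lambda`, variances, dispersions), the truncation trajectory
#'   `m_traj`, the alignment reference `Lambda_ref`, posterior-mean factor
#'   scores `Fmean`, the final state, and chain metadata.
#' @export
run_chain <- function(grex, Y, types, config = chain_config(),
                      covariates = NULL, seed = NULL) {
  grex <- as.matrix(grex); Y <- as.matrix(Y)
  .assert(nrow(grex) == nrow(Y), "grex and Y must have matching rows")
  .assert(ncol(Y) == length(types), "one type per phenotype required")
  .assert(all(is.finite(Y)), "phenotypes must be complete; missing values are not supported")
  type_code <- .type_codes(types)
  for (k in which(types == "binary"))
    .assert(all(Y[, k] %in% c(0, 1)), paste("binary phenotype", k, "must be 0/1"))
  for (k in which(types == "count"))
    .assert(all(Y[, k] >= 0 & Y[, k] == round(Y[, k])),
            paste("count phenotype", k, "must be non-negative integer"))
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    grex <- apply(grex, 2, function(v) residuals(lm(v ~ covariates)))
    for (k in which(types == "continuous"))
      Y[, k] <- residuals(lm(Y[, k] ~ covariates))
    if (any(types != "continuous"))
      message("covariates are residualized out of GReX and continuous ",
              "phenotypes only; discrete phenotypes are left unadjusted")
  }
  if (!.is_standardized(grex)) grex <- .standardize_cols(grex)
  for (k in which(types == "continuous")) Y[, k] <- Y[, k] - mean(Y[, k])

  n <- nrow(Y); q <- ncol(Y); p <- ncol(grex)
  m0 <- if (is.null(config$m_init)) min(q, 15) else min(config$m_init, q, n)
  m_max <- if (is.null(config$m_max)) q else config$m_max
  if (!is.null(seed)) set.seed(seed)
  state <- .init_state(grex, Y, types, m0, config)
  af <- .apply_fixed(state, config, p, q, m0)
  fit <- .joint_gibbs(grex, Y, unname(type_code), af$state,
                      .cpp_cfg(config, af$flags, m_max, config$iterations,
                               config$burnin, config$adapt))
  structure(list(
    B = fit$B, I = fit$I, U = fit$U, Lambda = fit$Lambda,
    omega2 = fit$omega2, tau2 = fit$tau2, r = fit$r, s2 = fit$s2,
    pi1 = fit$pi1, pi2 = fit$pi2, m_traj = as.vector(fit$m_traj),
    Fmean = fit$Fmean, Lambda_ref = fit$Lambda_ref, state = fit$state,
    n_draws = fit$n_kept, gene_ids = colnames(grex),
    phenotype_ids = colnames(Y), types = types,
    meta = list(iterations = config$iterations, burnin = config$burnin,
                thin = config$thin, seed = seed, m_final = fit$state$m)),
    class = "phenofm_draws")
}

#' One systematic Gibbs scan from a given state
#'
#' Advances the full joint state by a single sweep (optionally with the
#' adaptive truncation step) and returns the new state. This is the building
#' block used by simulation-consistency (Geweke-style) validation, where
#' sweeps alternate with re-simulation of the data.
#'
#' @param state full model state as returned in `$state` of [run_chain()] or
#'   built by hand (fields `I`, `U`, `b`, `pi1`, `pi2`, `s2`, `omega2`,
#'   `Lambda`, `F`, `phi`, `theta`, `tau2`, `r`).
#' @param grex,Y,types data as in [run_chain()].
#' @param config a [chain_config()]; its priors and `fixed` blocks apply.
#' @param adapt run the adaptation step this sweep.
#' @param sweep_index sweep counter used by the adaptation schedule.
#' @return the updated state list.
#' @export
gibbs_sweep <- function(state, grex, Y, types, config = chain_config(),
                        adapt = FALSE, sweep_index = 1) {
  .assert(sweep_index >= 1, "'sweep_index' must be >= 1")
  type_code <- .type_codes(types)
  q <- ncol(Y); p <- ncol(grex); m0 <- ncol(state$Lambda)
  af <- .apply_fixed(state, config, p, q, m0)
  m_max <- if (is.null(config$m_max)) q else config$m_max
  cfg <- .cpp_cfg(config, af$flags, m_max, n_iter = 1,
                  burn = if (adapt) 1 else 0, adapt = adapt)
  # fold the sweep index into the adaptation schedule's intercept
  cfg$alpha0 <- config$alpha0 + config$alpha1 * (sweep_index - 1)
  fit <- .joint_gibbs(as.matrix(grex), as.matrix(Y), unname(type_code),
                      af$state, cfg)
  fit$state
}

#' Probability of attempting a truncation adaptation at a given sweep
#'
#' @param sweep sweep index (>= 1).
#' @param alpha0,alpha1 schedule parameters; the probability
#'   `exp(-alpha0 - alpha1 sweep)` decreases in the sweep index.
#' @return adaptation probability.
#' @export
adapt_probability <- function(sweep, alpha0 = 1, alpha1 = 5e-4) {
  .assert(all(sweep >= 1), "'sweep' must be >= 1")
  exp(-alpha0 - alpha1 * sweep)
}

#' Align stored draws to a reference loading matrix
#'
#' Factor models are identified only up to column permutation and sign.
#' Each stored draw's loading columns are greedily matched to the reference
#' (largest absolute inner product first) with sign flips, and the same
#' permutation/flip is applied to `U`, `B` and `omega2`. Omnibus quantities
#' are invariant to this relabeling; factor-specific summaries require it.
#'
#' @param draws a `phenofm_draws` object.
#' @param reference loading matrix to align to; defaults to the last
#'   burn-in loadings stored on the object.
#' @return the draws object with aligned arrays (and `$alignment` recording
#'   permutations and signs).
#' @export
align_draws <- function(draws, reference = NULL) {
  if (is.null(reference)) reference <- draws$Lambda_ref
  m <- dim(draws$Lambda)[2]
  S <- draws$n_draws
  .assert(ncol(reference) == m, "reference has wrong number of columns")
  perms <- matrix(0L, S, m); signs <- matrix(1, S, m)
  for (s in seq_len(S)) {
    C <- crossprod(reference, draws$Lambda[, , s]) # m x m inner products
    perm <- integer(m); sgn <- numeric(m)
    A <- abs(C)
    for (step in seq_len(m)) {
      ij <- arrayInd(which.max(A), dim(A))
      i <- ij[1]; j <- ij[2]
      perm[i] <- j
      sgn[i] <- sign(C[i, j])
      if (sgn[i] == 0) sgn[i] <- 1
      A[i, ] <- -Inf; A[, j] <- -Inf
    }
    perms[s, ] <- perm; signs[s, ] <- sgn
    q <- dim(draws$Lambda)[1]; p <- dim(draws$B)[1]
    draws$Lambda[, , s] <- sweep(matrix(draws$Lambda[, perm, s], q, m),
                                 2, sgn, "*")
    draws$B[, , s] <- sweep(matrix(draws$B[, perm, s], p, m), 2, sgn, "*")
    draws$U[, , s] <- matrix(draws$U[, perm, s], p, m)
    draws$omega2[s, ] <- draws$omega2[s, perm]
  }
  draws$alignment <- list(reference = reference, perm = perms, sign = signs)
  draws
}

#' @export
print.phenofm_draws <- function(x, ...) {
  cat("Joint fine-mapping posterior draws: ", x$n_draws, " stored sweeps, ",
      length(x$gene_ids), " genes, ", length(x$phenotype_ids),
      " phenotypes, final truncation m = ", x$meta$m_final, "\n", sep = "")
  invisible(x)
}
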