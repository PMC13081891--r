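# shared small fixtures and utilities

# standardized design matrix without scale() attribute baggage
std_matrix <- function(n, p, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  M <- scale(matrix(rnorm(n * p), n, p))
  attr(M, "scaled:center") <- NULL
  attr(M, "scaled:scale") <- NULL
  M
}

# a tiny synthetic study for smoke tests
tiny_study <- function(scenario = "homogeneous", seed = 5, q = 9, n2 = 400) {
  simulate_study(sim_config(scenario = scenario, n1 = 120, n2 = n2,
                            n_regions = 1, genes_per_region = 5,
                            snps_per_gene = 5, q = q, m = 2, h2 = 0.1,
                            seed = seed))
}

# fast chain settings for smoke tests
quick_chain <- function(...) {
  args <- modifyList(list(iterations = 300, burnin = 100, thin = 2,
                          m_init = 3, m_max = 6, adapt_eps = 0.1), list(...))
  do.call(chain_config, args)
}

# build a phenofm_draws object from explicit indicator/effect arrays,
# for testing PIP and reporting logic independently of the sampler
fake_draws <- function(B, I, U, Lambda, gene_ids = NULL, phenotype_ids = NULL) {
  S <- dim(B)[3]
  structure(list(
    B = B, I = I, U = U, Lambda = Lambda,
    omega2 = matrix(1, S, dim(B)[2]), tau2 = matrix(1, S, dim(Lambda)[1]),
    r = matrix(1, S, dim(Lambda)[1]), s2 = rep(1, S), pi1 = rep(0.5, S),
    pi2 = rep(0.5, S), m_traj = rep(dim(B)[2], S),
    Fmean = matrix(0, 2, dim(B)[2]),
    Lambda_ref = matrix(Lambda[, , S], dim(Lambda)[1], dim(Lambda)[2]),
    state = list(m = dim(B)[2]), n_draws = S,
    gene_ids = gene_ids %||% paste0("g", seq_len(dim(B)[1])),
    phenotype_ids = phenotype_ids %||% paste0("p", seq_len(dim(Lambda)[1])),
    types = rep("continuous", dim(Lambda)[1]),
    meta = list(iterations = S, burnin = 0, thin = 1, seed = 1,
                m_final = dim(B)[2])),
    class = "phenofm_draws")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
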