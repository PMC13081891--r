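# per-gene spike-and-slab expression model, GReX imputation, weight IO

test_that("posterior spike pattern matches exhaustive enumeration (g = 2)", {
  set.seed(42)
  n <- 60
  Z <- std_matrix(n, 2)
  x <- 0.8 * Z[, 1] + rnorm(n, sd = 0.8)
  pi0 <- 0.5; v2 <- 1; s2 <- 0.64
  logml <- function(slab) {
    S <- diag(s2, n)
    if (any(slab))
      S <- S + v2 * s2 * tcrossprod(Z[, slab, drop = FALSE])
    -0.5 * (determinant(S)$modulus + drop(t(x) %*% solve(S, x)))
  }
  pats <- expand.grid(s1 = c(FALSE, TRUE), s2 = c(FALSE, TRUE))
  lp <- apply(pats, 1, function(r) logml(as.logical(r)) +
                sum(ifelse(as.logical(r), log(1 - pi0), log(pi0))))
  post <- exp(lp - max(lp)); post <- post / sum(post)
  p_slab <- c(sum(post[pats$s1]), sum(post[pats$s2]))
  fit <- fit_gene_weights(x, Z, mcmc = expr_mcmc(
    iterations = 22000, burnin = 2000, thin = 1,
    fix_pi = pi0, fix_v2 = v2, fix_sigma2 = s2))
  expect_lt(max(abs((1 - fit$spike_prob) - p_slab)), 0.03)
})

test_that("perfect signal drives the effect to 1 and the spike off", {
  set.seed(1)
  Z <- std_matrix(250, 3)
  x <- Z[, 1] # exact, no noise
  fit <- fit_gene_weights(x, Z, mcmc = expr_mcmc(iterations = 3000,
                                                 burnin = 1000, thin = 1))
  expect_lt(abs(fit$gamma_hat[1] - 1), 0.02)
  expect_lt(fit$spike_prob[1], 0.02)
})

test_that("a null gene's effects shrink toward zero", {
  set.seed(2)
  Z <- std_matrix(250, 10)
  x <- rnorm(250)
  fit <- fit_gene_weights(x, Z, mcmc = expr_mcmc(iterations = 6000,
                                                 burnin = 2000, thin = 1))
  expect_true(all(abs(fit$gamma_hat) < 0.1 * sd(x)))
})

test_that("posterior mean shrinks monotonically in the spike probability", {
  # 1-SNP conjugate case with all hyperparameters fixed: closed form
  set.seed(3)
  n <- 120
  Z <- std_matrix(n, 1)
  x <- 0.3 * Z[, 1] + rnorm(n, sd = 0.9)
  v2 <- 1; s2 <- 0.81
  z <- sum(Z[, 1] * x) / s2
  P <- sum(Z[, 1]^2) / s2 + 1 / (v2 * s2)
  logbf <- -0.5 * log(v2 * s2 * P) + 0.5 * z^2 / P
  means <- vapply(c(0.2, 0.5, 0.8), function(pi0) {
    fit <- fit_gene_weights(x, Z, mcmc = expr_mcmc(
      iterations = 22000, burnin = 2000, thin = 1,
      fix_pi = pi0, fix_v2 = v2, fix_sigma2 = s2))
    w_slab <- 1 / (1 + exp(-(log((1 - pi0) / pi0) + logbf)))
    expect_lt(abs(fit$gamma_hat[1] - w_slab * z / P), 0.02)
    abs(fit$gamma_hat[1])
  }, 0)
  expect_true(all(diff(means) < 0.005)) # non-increasing up to MC error
})

test_that("degenerate inputs are handled explicitly", {
  Z <- cbind(std_matrix(50, 2, seed = 4), 0)
  colnames(Z) <- paste0("s", 1:3)
  expect_warning(fit_gene_weights(rnorm(50), Z,
                                  mcmc = expr_mcmc(400, 100, 1)),
                 "zero-variance")
  expect_error(fit_gene_weights(c(1, 2), matrix(1:2)), "3 reference")
  expect_error(fit_gene_weights(c(1, NA, 3), matrix(rnorm(9), 3)), "finite")
})

test_that("imputation equals the direct matrix product, standardized", {
  set.seed(5)
  Zg <- std_matrix(100, 6)
  colnames(Zg) <- paste0("rs", 1:6)
  w <- structure(list(gene_id = "gA", snp_ids = paste0("rs", c(2, 5)),
                      gamma_hat = c(rs2 = 0.4, rs5 = -1.1),
                      spike_prob = c(0.1, 0.2), sigma2_hat = 1, v2_hat = 1,
                      pi_hat = 0.5), class = "phenofm_weights")
  grex <- impute_grex(Zg, w)
  raw <- Zg[, c(2, 5)] %*% c(0.4, -1.1)
  expect_lt(max(abs(grex[, "gA"] - (raw - mean(raw)) / sd(raw))), 1e-10)

  # single SNP with weight 1: the standardized SNP column itself
  w1 <- structure(list(gene_id = "gB", snp_ids = "rs1",
                       gamma_hat = c(rs1 = 1), spike_prob = 0,
                       sigma2_hat = 1, v2_hat = 1, pi_hat = 0.5),
                  class = "phenofm_weights")
  expect_equal(unname(impute_grex(Zg, w1)[, "gB"]), unname(Zg[, "rs1"]),
               tolerance = 1e-10)
})

test_that("zero-weight genes are dropped and missing SNPs are keyed errors", {
  Zg <- std_matrix(50, 3, seed = 6)
  colnames(Zg) <- paste0("rs", 1:3)
  wz <- structure(list(gene_id = "gZ", snp_ids = "rs1",
                       gamma_hat = c(rs1 = 0), spike_prob = 1,
                       sigma2_hat = 1, v2_hat = 1, pi_hat = 0.5),
                  class = "phenofm_weights")
  wa <- structure(list(gene_id = "gA", snp_ids = "rs2",
                       gamma_hat = c(rs2 = 1), spike_prob = 0,
                       sigma2_hat = 1, v2_hat = 1, pi_hat = 0.5),
                  class = "phenofm_weights")
  expect_warning(out <- impute_grex(Zg, list(wz, wa)), "gZ")
  expect_identical(colnames(out), "gA")
  wmiss <- structure(list(gene_id = "gM", snp_ids = "rs99",
                          gamma_hat = c(rs99 = 1), spike_prob = 0,
                          sigma2_hat = 1, v2_hat = 1, pi_hat = 0.5),
                     class = "phenofm_weights")
  expect_error(impute_grex(Zg, wmiss), "gM.*rs99")
})

test_that("weight tables round-trip through the TSV dialect", {
  set.seed(7)
  Z <- std_matrix(100, 4)
  colnames(Z) <- paste0("rs", 1:4)
  x <- Z %*% c(1, 0, 0, 0) + rnorm(100, sd = 0.5)
  w <- fit_gene_weights(as.vector(x), Z, gene_id = "geneX",
                        mcmc = expr_mcmc(800, 300, 1))
  path <- tempfile(fileext = ".tsv")
  write_weights(w, path)
  back <- read_weights(path)
  expect_length(back, 1)
  expect_equal(back[[1]]$gamma_hat, w$gamma_hat, tolerance = 1e-12)
  expect_equal(back[[1]]$snp_ids, w$snp_ids)

  # empty file: empty list, no error
  empty <- tempfile(fileext = ".tsv")
  writeLines("gene\trsid\tweight", empty)
  expect_identical(read_weights(empty), list())

  # duplicated (gene, rsid) is a format error naming the line
  dup <- tempfile(fileext = ".tsv")
  writeLines(c("gene\trsid\tweight", "g1\trs1\t0.5", "g1\trs1\t0.7"), dup)
  expect_error(read_weights(dup), "duplicated.*line 3")

  # malformed header is a format error
  badh <- tempfile(fileext = ".tsv")
  writeLines(c("gene\tsnp\tw", "g1\trs1\t0.5"), badh)
  expect_error(read_weights(badh), "header")

  # unknown columns survive a round trip
  extra <- tempfile(fileext = ".tsv")
  writeLines(c("gene\trsid\tweight\tnote", "g1\trs1\t0.5\thello"), extra)
  back2 <- read_weights(extra)
  expect_identical(attr(back2[[1]], "extra")$note, "hello")
  out2 <- tempfile(fileext = ".tsv")
  write_weights(back2, out2)
  expect_identical(attr(read_weights(out2)[[1]], "extra")$note, "hello")
})
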