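# synthetic-data generator: genotype LD, expression architecture, scenario
# contracts and determinism

test_that("config validation enforces the documented invariants", {
  cfg <- sim_config()
  expect_s3_class(cfg, "phenofm_sim_config")
  expect_equal(cfg$n1, 250)
  expect_equal(cfg$n2, 5000)
  expect_equal(cfg$n_regions, 10)
  expect_equal(cfg$genes_per_region, 10)
  expect_equal(cfg$snps_per_gene, 10)
  expect_equal(cfg$q, 50)
  expect_error(sim_config(h2 = 0), "h2")
  expect_error(sim_config(h2 = 1), "h2")
  expect_error(sim_config(q = 2, m = 3), "at least")
  expect_error(sim_config(ld_rho = 1), "ld_rho")
  expect_error(sim_config(n_causal_snps = 11), "causal SNPs")
  expect_error(sim_config(type_mix = rep("continuous", 3), q = 50), "type")
})

test_that("independent SNPs have near-zero pairwise dosage correlations", {
  Z <- simulate_genotypes(200, 10, ld_rho = 0, maf_range = c(0.05, 0.5),
                          seed = 1)
  D <- attr(Z, "dosage")
  expect_true(all(D %in% 0:2))
  cc <- cor(Z)
  expect_lt(max(abs(cc[upper.tri(cc)])), 4 / sqrt(200))
  expect_lt(max(abs(colMeans(Z))), 1e-8)
  expect_equal(unname(apply(Z, 2, sd)), rep(1, 10), tolerance = 1e-8)
})

test_that("realized LD matches the thresholded-bivariate-normal oracle", {
  Z <- simulate_genotypes(2000, 2, ld_rho = 0.9, seed = 7)
  maf <- attr(Z, "maf"); D <- attr(Z, "dosage")
  t1 <- qnorm(1 - maf[1]); t2 <- qnorm(1 - maf[2]); rho <- 0.9
  # P(X1 > t1, X2 > t2) by numeric integration of the conditional normal
  p11 <- integrate(function(z)
    dnorm(z) * pnorm((t2 - rho * z) / sqrt(1 - rho^2), lower.tail = FALSE),
    t1, Inf)$value
  r_oracle <- (p11 - prod(maf)) /
    sqrt(maf[1] * (1 - maf[1]) * maf[2] * (1 - maf[2]))
  expect_lt(abs(cor(D[, 1], D[, 2]) - r_oracle), 0.1)
})

test_that("genotype simulation is deterministic and validates inputs", {
  a <- simulate_genotypes(50, 5, 0.3, seed = 3)
  b <- simulate_genotypes(50, 5, 0.3, seed = 3)
  expect_identical(a, b)
  expect_error(simulate_genotypes(1, 5), "n >= 2")
  expect_error(simulate_genotypes(10, 5, ld_rho = 1.2), "ld_rho")
  expect_error(simulate_genotypes(10, 5, maf_range = c(0, 0.5)), "maf_range")
})

test_that("expression model hits its genetic-variance target", {
  Z <- simulate_genotypes(5000, 10, ld_rho = 0.5, seed = 9)
  # null architecture: no genetic component at all
  s0 <- simulate_expression(Z, 0, 0, seed = 1)
  expect_true(all(s0$gamma == 0))
  # sparse architecture: exactly n_causal nonzero effects, R^2 near target
  r2 <- replicate(20, {
    s <- simulate_expression(Z, 3, 0.3)
    summary(lm(s$expression ~ as.vector(Z %*% s$gamma)))$r.squared
  })
  s <- simulate_expression(Z, 3, 0.3, seed = 2)
  expect_equal(sum(s$gamma != 0), 3)
  expect_lt(abs(mean(r2) - 0.3), 0.05)
  expect_error(simulate_expression(Z, 0, 0.5), "causal")
})

test_that("scenario contracts hold for causal-set structure", {
  st_h <- simulate_study(sim_config(scenario = "homogeneous", n1 = 80,
                                    n2 = 150, n_regions = 3,
                                    genes_per_region = 4, snps_per_gene = 3,
                                    q = 6, m = 3, seed = 2))
  sets <- st_h$truth$causal_sets
  expect_true(all(vapply(sets, identical, logical(1), sets[[1]])))
  # per-region causal count is 1 or 2
  reg <- (sets[[1]] - 1) %/% 4 + 1
  expect_true(all(table(reg) %in% 1:2))
  expect_true(all(1:3 %in% reg))

  st_het <- simulate_study(sim_config(scenario = "heterogeneous", n1 = 80,
                                      n2 = 150, n_regions = 3,
                                      genes_per_region = 4,
                                      snps_per_gene = 3, q = 6, m = 3,
                                      seed = 2))
  expect_gte(length(unique(st_het$truth$causal_sets)), 2)

  st_null <- simulate_study(sim_config(scenario = "null", n1 = 80, n2 = 150,
                                       n_regions = 3, genes_per_region = 4,
                                       snps_per_gene = 3, q = 6, m = 3,
                                       seed = 2))
  expect_true(all(st_null$truth$true_B == 0))
  expect_length(st_null$truth$causal_genes, 0)
})

test_that("true_B support matches the causal sets", {
  st <- simulate_study(sim_config(scenario = "heterogeneous", n1 = 80,
                                  n2 = 200, n_regions = 2,
                                  genes_per_region = 5, snps_per_gene = 3,
                                  q = 8, m = 2, seed = 4))
  for (l in seq_len(2))
    expect_identical(sort(which(st$truth$true_B[, l] != 0)),
                     sort(st$truth$causal_sets[[l]]))
  # every phenotype loads on at most 2 and at least 1 factor
  nl <- rowSums(st$truth$true_Lambda != 0)
  expect_true(all(nl >= 1 & nl <= 2))
})

test_that("null phenotypes are independent of GReX", {
  st <- simulate_study(sim_config(scenario = "null", n1 = 80, n2 = 1500,
                                  n_regions = 2, genes_per_region = 5,
                                  snps_per_gene = 3, q = 9, m = 2,
                                  type_mix = "continuous", seed = 6))
  cc <- abs(cor(st$grex_true, st$phenotypes$Y))
  expect_lt(mean(cc), 3 / sqrt(1500))
})

test_that("a full study is a deterministic function of its configuration", {
  cfg <- sim_config(n1 = 60, n2 = 120, n_regions = 2, genes_per_region = 3,
                    snps_per_gene = 4, q = 6, m = 2, seed = 11)
  a <- simulate_study(cfg); b <- simulate_study(cfg)
  expect_identical(a, b)
  # mixed default interleaves the three outcome types
  expect_setequal(unique(a$phenotypes$types),
                  c("continuous", "binary", "count"))
  # gene map partitions genes into contiguous region blocks
  expect_identical(a$gene_map$region, rep(1:2, each = 3))
  # genotype columns standardized
  expect_lt(max(abs(colMeans(a$gwas_genotypes))), 1e-8)
})

test_that("realized GReX-explained variance tracks the target", {
  st <- simulate_study(sim_config(scenario = "homogeneous", n1 = 150,
                                  n2 = 3000, q = 12, m = 2, h2 = 0.05,
                                  n_regions = 3, genes_per_region = 5,
                                  type_mix = "continuous", seed = 13))
  expect_lt(abs(mean(st$truth$realized_h2) - 0.05), 0.02)
})
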