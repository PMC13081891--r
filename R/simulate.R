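#' Configuration for the synthetic phenome-wide TWAS study
#'
#' Collects the knobs of the data generator. Defaults reproduce the study
#' conditions of the simulation design: a reference panel of `n1 = 250`, a
#' GWAS cohort of `n2 = 5000`, 10 regions of 10 genes with 10 cis-SNPs each,
#' `q = 50` phenotypes generated from `m` latent factors at GReX-explained
#' variance fraction (heritability) `h2`, and an average of 1-2 causal genes
#' per region (drawn uniformly from {1, 2}).
#'
#' @param scenario `"homogeneous"` (all factors share one causal gene set),
#'   `"heterogeneous"` (causal sets differ across factors) or `"null"`
#'   (no causal genes).
#' @param n1,n2 reference-panel and GWAS sample sizes.
#' @param n_regions,genes_per_region,snps_per_gene region architecture.
#' @param q number of phenotypes; `m` number of true latent factors.
#' @param h2 fraction of phenotypic variance explained by GReX (on the latent
#'   linear-predictor scale for discrete outcomes), in (0, 1).
#' @param h2_expr fraction of expression variance explained by cis-SNPs.
#' @param n_causal_snps causal cis-SNPs per gene.
#' @param ld_rho lag-1 correlation of the latent AR(1) genotype process.
#' @param maf_range range from which per-SNP minor-allele frequencies are drawn.
#' @param type_mix `"mixed"` (continuous/binary/count interleaved),
#'   `"continuous"`, or a character vector of length `q` of per-column types.
#' @param causal_per_region mean causal genes per region: `1.5` (the default)
#'   draws the per-region count uniformly from {1, 2}; an integer fixes it.
#' @param r_nb true negative-binomial dispersion for count phenotypes.
#' @param seed integer seed; the full study is a deterministic function of the
#'   configuration including the seed.
#' @return a `phenofm_sim_config` list.
#' @export
sim_config <- function(scenario = c("homogeneous", "heterogeneous", "null"),
                       n1 = 250, n2 = 5000, n_regions = 10,
                       genes_per_region = 10, snps_per_gene = 10,
                       q = 50, m = 3, h2 = 0.05, h2_expr = 0.3,
                       n_causal_snps = 3, ld_rho = 0.8,
                       maf_range = c(0.05, 0.5), type_mix = "mixed",
                       causal_per_region = 1.5, r_nb = 2, seed = 1) {
  scenario <- match.arg(scenario)
  counts <- c(n1 = n1, n2 = n2, n_regions = n_regions,
              genes_per_region = genes_per_region,
              snps_per_gene = snps_per_gene, q = q, m = m)
  .assert(all(counts >= 1) && all(counts == round(counts)),
          "all counts must be integers >= 1")
  .assert(h2 > 0 && h2 < 1, "'h2' must be in (0, 1)")
  .assert(h2_expr >= 0 && h2_expr < 1, "'h2_expr' must be in [0, 1)")
  .assert(ld_rho >= 0 && ld_rho < 1, "'ld_rho' must be in [0, 1)")
  .assert(length(maf_range) == 2 && maf_range[1] > 0 && maf_range[2] <= 0.5 &&
            maf_range[1] <= maf_range[2], "invalid 'maf_range'")
  .assert(n_causal_snps <= snps_per_gene, "more causal SNPs than cis-SNPs")
  .assert(q >= m, "'q' must be at least 'm'")
  .assert(causal_per_region >= 1 && causal_per_region <= genes_per_region,
          "'causal_per_region' out of range")
  if (length(type_mix) == 1 && type_mix %in% c("mixed", "continuous")) {
    types <- if (type_mix == "continuous") rep("continuous", q)
             else rep_len(c("continuous", "binary", "count"), q)
  } else {
    .assert(length(type_mix) == q &&
              all(type_mix %in% c("continuous", "binary", "count")),
            "'type_mix' must name a valid type for each of the q phenotypes")
    types <- type_mix
  }
  structure(list(scenario = scenario, n1 = n1, n2 = n2, n_regions = n_regions,
                 genes_per_region = genes_per_region,
                 snps_per_gene = snps_per_gene, q = q, m = m, h2 = h2,
                 h2_expr = h2_expr, n_causal_snps = n_causal_snps,
                 ld_rho = ld_rho, maf_range = maf_range, types = types,
                 causal_per_region = causal_per_region,
                 r_nb = r_nb, seed = as.integer(seed)),
            class = "phenofm_sim_config")
}

#' Simulate standardized genotype dosages with tunable LD
#'
#' Dosages in `{0, 1, 2}` are generated as the sum of two independent
#' haplotypes, each obtained by thresholding a latent Gaussian AR(1) process
#' (lag-1 correlation `ld_rho`) at the quantile of a per-SNP minor-allele
#' frequency drawn uniformly from `maf_range`. Columns are then standardized
#' to mean zero and unit sample variance.
#'
#' @param n number of individuals (>= 2).
#' @param g number of SNPs.
#' @param ld_rho latent AR(1) lag-1 correlation in `[0, 1)`.
#' @param maf_range MAF range.
#' @param seed optional seed (draws are part of the caller's RNG stream when
#'   omitted).
#' @param maf optional vector of fixed per-SNP MAFs (used to generate matched
#'   reference/GWAS panels); overrides `maf_range`.
#' @return an `n x g` standardized dosage matrix with attributes `maf` and
#'   `dosage` (the raw 0/1/2 matrix).
#' @export
simulate_genotypes <- function(n, g, ld_rho = 0, maf_range = c(0.05, 0.5),
                               seed = NULL, maf = NULL) {
  .assert(is.finite(n) && n >= 2 && is.finite(g) && g >= 1,
          "need n >= 2 individuals and g >= 1 SNPs")
  .assert(is.finite(ld_rho) && ld_rho >= 0 && ld_rho < 1,
          "'ld_rho' must be in [0, 1)")
  .assert(all(is.finite(maf_range)) && maf_range[1] > 0 && maf_range[2] <= 0.5,
          "'maf_range' must lie in (0, 0.5]")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(maf)) maf <- runif(g, maf_range[1], maf_range[2])
  .assert(length(maf) == g && all(maf > 0 & maf <= 0.5), "invalid 'maf'")
  thr <- qnorm(1 - maf)
  hap <- function() {
    L <- matrix(rnorm(n * g), n, g)
    if (ld_rho > 0 && g > 1) {
      sc <- sqrt(1 - ld_rho^2)
      for (j in 2:g) L[, j] <- ld_rho * L[, j - 1] + sc * L[, j]
    }
    L
  }
  dosage <- (hap() > rep(thr, each = n)) + (hap() > rep(thr, each = n))
  storage.mode(dosage) <- "double"
  # a monomorphic draw (possible at small n and low MAF) cannot be
  # standardized; redraw that SNP's alleles independently
  for (j in seq_len(g)) {
    tries <- 0
    while (var(dosage[, j]) == 0 && tries < 50) {
      dosage[, j] <- rbinom(n, 2, maf[j])
      tries <- tries + 1
    }
    if (var(dosage[, j]) == 0) dosage[, j] <- rbinom(n, 2, 0.5)
  }
  Z <- .standardize_cols(dosage)
  attr(Z, "maf") <- maf
  attr(Z, "dosage") <- dosage
  attr(Z, "constant_columns") <- NULL
  Z
}

#' Simulate one gene's expression from its cis-SNPs
#'
#' Draws a sparse cis-eQTL effect vector with exactly `n_causal_snps` nonzero
#' entries, scaled so the genetic component `Z gamma` has sample variance
#' `h2_expr`, and adds Gaussian noise of variance `1 - h2_expr`.
#'
#' @param Z_ref standardized reference-panel genotypes (`n1 x g`).
#' @param n_causal_snps number of causal cis-SNPs (0 allowed only with
#'   `h2_expr = 0`).
#' @param h2_expr expression variance fraction from cis-SNPs, in `[0, 1)`.
#' @param seed optional seed.
#' @return list with `expression` (length-`n1` vector) and `gamma` (true
#'   effect vector, length `g`).
#' @export
simulate_expression <- function(Z_ref, n_causal_snps, h2_expr, seed = NULL) {
  .assert(h2_expr >= 0 && h2_expr < 1, "'h2_expr' must be in [0, 1)")
  g <- ncol(Z_ref)
  .assert(n_causal_snps <= g, "more causal SNPs than columns of Z_ref")
  .assert(h2_expr == 0 || n_causal_snps >= 1,
          "positive 'h2_expr' requires at least one causal SNP")
  if (!is.null(seed)) set.seed(seed)
  gamma <- numeric(g)
  if (h2_expr > 0) {
    idx <- sample.int(g, n_causal_snps)
    gamma[idx] <- rnorm(n_causal_snps)
    gvec <- as.vector(Z_ref %*% gamma)
    s <- sd(gvec)
    if (s > 0) gamma <- gamma * sqrt(h2_expr) / s
  }
  x <- as.vector(Z_ref %*% gamma) + rnorm(nrow(Z_ref), sd = sqrt(1 - h2_expr))
  list(expression = x, gamma = gamma)
}

# causal gene sets: per region 1 or 2 causal genes, drawn uniformly
.draw_causal_sets <- function(config) {
  p_t <- config$genes_per_region
  T_ <- config$n_regions
  cpr <- config$causal_per_region
  one_set <- function() {
    unlist(lapply(seq_len(T_), function(t) {
      ct <- if (cpr == round(cpr)) as.integer(cpr)
            else sample(floor(cpr):ceiling(cpr), 1)
      as.integer((t - 1) * p_t) + sample.int(p_t, ct)
    }))
  }
  if (config$scenario == "null") return(rep(list(integer(0)), config$m))
  if (config$scenario == "homogeneous") {
    s <- sort(one_set())
    return(rep(list(s), config$m))
  }
  repeat { # heterogeneous: require at least two distinct sets
    sets <- lapply(seq_len(config$m), function(l) sort(one_set()))
    if (config$m == 1 || length(unique(sets)) >= 2) return(sets)
  }
}

#' Simulate phenotypes from latent factors driven by GReX
#'
#' Builds `m` latent factors `f_l = sum_{j in C_l} beta_jl xhat_j + eps_l`
#' with the genetic component scaled to sample variance `h2` and
#' `eps_l ~ N(0, 1 - h2)`; each phenotype loads on one or two factors with
#' N(0,1) loadings, and receives idiosyncratic Gaussian noise whose variance
#' is set so the realized GReX-explained fraction of its latent predictor
#' equals `h2`. Predictors are rescaled to unit sample variance. Continuous
#' phenotypes are the predictor itself; binary phenotypes are
#' `Bernoulli(logit^-1(predictor))`; counts are negative binomial with
#' `mu = r_nb exp(predictor)` (success probability `logit^-1(predictor)`),
#' matching the augmented likelihood of the fine-mapping model.
#'
#' @param grex standardized true GReX matrix (`n2 x p`).
#' @param config a [sim_config()].
#' @param seed optional seed.
#' @return list with `phenotypes` (list: `Y` matrix, `types`) and `truth`
#'   (causal sets, `true_B`, `true_Lambda`, `true_F`, realized per-phenotype
#'   GReX variance fractions).
#' @export
simulate_phenotypes <- function(grex, config, seed = NULL) {
  .assert(inherits(config, "phenofm_sim_config"), "'config' must come from sim_config()")
  .assert(config$q >= config$m, "q < m")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(grex); p <- ncol(grex)
  m <- config$m; q <- config$q; h2 <- config$h2
  causal_sets <- .draw_causal_sets(config)

  B <- matrix(0, p, m)
  G <- matrix(0, n, m) # genetic component of each factor
  Fmat <- matrix(0, n, m)
  for (l in seq_len(m)) {
    C_l <- causal_sets[[l]]
    if (length(C_l) > 0) {
      B[C_l, l] <- rnorm(length(C_l))
      gl <- as.vector(grex %*% B[, l])
      B[, l] <- B[, l] * sqrt(h2) / sd(gl)
      G[, l] <- as.vector(grex %*% B[, l])
      Fmat[, l] <- G[, l] + rnorm(n, sd = sqrt(1 - h2))
    } else {
      Fmat[, l] <- rnorm(n)
    }
  }

  # sparse loadings: primary factor round-robin, optional second factor
  Lambda <- matrix(0, q, m)
  for (k in seq_len(q)) {
    act <- ((k - 1) %% m) + 1
    if (m > 1 && runif(1) < 0.5) act <- c(act, sample(setdiff(seq_len(m), act), 1))
    Lambda[k, act] <- rnorm(length(act))
  }

  Y <- matrix(0, n, q)
  realized <- numeric(q)
  null_case <- config$scenario == "null"
  for (k in seq_len(q)) {
    fac <- as.vector(Fmat %*% Lambda[k, ])
    gen <- as.vector(G %*% Lambda[k, ])
    if (null_case) {
      tau2 <- 0.5 * max(var(fac), 1e-12)
    } else {
      target_total <- var(gen) / h2
      tau2 <- max(target_total - var(fac), 0.05 * target_total)
    }
    e <- rnorm(n, sd = sqrt(tau2))
    pred <- fac + e
    s <- sd(pred)
    pred <- pred / s
    Lambda[k, ] <- Lambda[k, ] / s
    realized[k] <- if (null_case) 0 else var(gen / s) / var(pred)
    Y[, k] <- switch(config$types[k],
      continuous = pred,
      binary = rbinom(n, 1, plogis(pred)),
      count = rnbinom(n, size = config$r_nb, mu = config$r_nb * exp(pred)))
  }

  truth <- list(causal_sets = causal_sets,
                causal_genes = sort(unique(unlist(causal_sets))),
                true_B = B, true_Lambda = Lambda, true_F = Fmat,
                realized_h2 = realized, r_nb = config$r_nb)
  list(phenotypes = list(Y = Y, types = config$types), truth = truth)
}

#' Simulate a complete synthetic TWAS study with known ground truth
#'
#' Generates matched reference-panel and GWAS genotypes (same MAFs and LD
#' process, independent individuals), reference expression for every gene,
#' the true GReX in the GWAS cohort, and mixed-type phenotypes driven by
#' latent factors, together with the full generative truth.
#'
#' @param config a [sim_config()].
#' @return a `phenofm_study` list: `ref_genotypes`, `gwas_genotypes`
#'   (standardized, SNP columns named `r<region>g<gene>s<snp>`),
#'   `ref_expression` (`n1 x p`), `grex_true` (standardized true GReX,
#'   `n2 x p`), `phenotypes`, `gene_map` (gene, region, snps), `truth`,
#'   and the `config`.
#' @export
simulate_study <- function(config = sim_config()) {
  .assert(inherits(config, "phenofm_sim_config"), "'config' must come from sim_config()")
  set.seed(config$seed)
  T_ <- config$n_regions; p_t <- config$genes_per_region
  g_j <- config$snps_per_gene
  p <- T_ * p_t
  gene_ids <- paste0("gene_r", rep(seq_len(T_), each = p_t), "_",
                     rep(seq_len(p_t), T_))
  Zr_list <- vector("list", T_); Zg_list <- vector("list", T_)
  for (t in seq_len(T_)) {
    gsnp <- p_t * g_j
    maf <- runif(gsnp, config$maf_range[1], config$maf_range[2])
    Zr_list[[t]] <- simulate_genotypes(config$n1, gsnp, config$ld_rho, maf = maf)
    Zg_list[[t]] <- simulate_genotypes(config$n2, gsnp, config$ld_rho, maf = maf)
    snp_ids <- paste0("r", t, "g", rep(seq_len(p_t), each = g_j), "s",
                      rep(seq_len(g_j), p_t))
    colnames(Zr_list[[t]]) <- snp_ids
    colnames(Zg_list[[t]]) <- snp_ids
  }
  Zr <- do.call(cbind, Zr_list)
  Zg <- do.call(cbind, Zg_list)

  expr <- matrix(0, config$n1, p, dimnames = list(NULL, gene_ids))
  grex_true <- matrix(0, config$n2, p, dimnames = list(NULL, gene_ids))
  gamma_list <- vector("list", p)
  snps_of_gene <- vector("list", p)
  for (j in seq_len(p)) {
    t <- (j - 1) %/% p_t + 1
    jr <- (j - 1) %% p_t
    cols <- (t - 1) * p_t * g_j + jr * g_j + seq_len(g_j)
    snps_of_gene[[j]] <- colnames(Zr)[cols]
    sim <- simulate_expression(Zr[, cols, drop = FALSE],
                               config$n_causal_snps, config$h2_expr)
    expr[, j] <- sim$expression
    gamma_list[[j]] <- setNames(sim$gamma, snps_of_gene[[j]])
    grex_true[, j] <- Zg[, cols, drop = FALSE] %*% sim$gamma
  }
  grex_true <- .standardize_cols(grex_true)

  ph <- simulate_phenotypes(grex_true, config)
  ph$truth$true_gamma <- gamma_list
  colnames(ph$phenotypes$Y) <- paste0("pheno_", seq_len(config$q))

  gene_map <- data.frame(gene = gene_ids,
                         region = rep(seq_len(T_), each = p_t),
                         snps = vapply(snps_of_gene, paste, "", collapse = ","),
                         stringsAsFactors = FALSE)
  structure(list(ref_genotypes = Zr, gwas_genotypes = Zg,
                 ref_expression = expr, grex_true = grex_true,
                 phenotypes = ph$phenotypes, gene_map = gene_map,
                 truth = ph$truth, config = config),
            class = "phenofm_study")
}

#' @export
print.phenofm_study <- function(x, ...) {
  cfg <- x$config
  cat("Synthetic phenome-wide TWAS study (", cfg$scenario, " scenario)\n",
      "  reference n1 = ", cfg$n1, ", GWAS n2 = ", cfg$n2, "\n",
      "  ", cfg$n_regions, " regions x ", cfg$genes_per_region, " genes x ",
      cfg$snps_per_gene, " cis-SNPs; q = ", cfg$q, " phenotypes, m = ",
      cfg$m, " factors, h2 = ", cfg$h2, "\n", sep = "")
  invisible(x)
}
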