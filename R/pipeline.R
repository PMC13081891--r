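#' Rank-based area under the ROC curve
#'
#' Mann-Whitney AUC of `scores` against binary `labels`, with midrank tie
#' handling; equals the probability that a random positive outranks a random
#' negative.
#'
#' @param scores numeric scores (e.g. omnibus PIPs).
#' @param labels logical or 0/1 truth labels.
#' @return AUC in `[0, 1]`; `NA` when either class is empty.
#' @export
auc_rank <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# F-score of recovered loading support against the truth, with greedy
# matching of estimated to true factor columns (|correlation| of posterior
# means), counting unmatched columns' support as misses/false calls
.loading_fscore <- function(lam_mean, support_prob, true_Lambda, eps = 1e-2) {
  est_support <- support_prob > 0.5
  true_support <- abs(true_Lambda) > eps
  m_est <- ncol(lam_mean); m_true <- ncol(true_Lambda)
  C <- abs(suppressWarnings(cor(lam_mean, true_Lambda)))
  C[!is.finite(C)] <- 0
  tp <- 0L; fp <- 0L; fn <- 0L
  used_e <- logical(m_est); used_t <- logical(m_true)
  for (step in seq_len(min(m_est, m_true))) {
    ij <- arrayInd(which.max(ifelse(outer(!used_e, !used_t, "&"), C, -1)),
                   dim(C))
    e <- ij[1]; t <- ij[2]
    if (used_e[e] || used_t[t]) break
    used_e[e] <- TRUE; used_t[t] <- TRUE
    tp <- tp + sum(est_support[, e] & true_support[, t])
    fp <- fp + sum(est_support[, e] & !true_support[, t])
    fn <- fn + sum(!est_support[, e] & true_support[, t])
  }
  fp <- fp + sum(est_support[, !used_e, drop = FALSE])
  fn <- fn + sum(true_support[, !used_t, drop = FALSE])
  if (2 * tp + fp + fn == 0) return(NA_real_)
  2 * tp / (2 * tp + fp + fn)
}

# train spike-and-slab weights for every gene of a study
.train_study_weights <- function(study, mcmc, seed) {
  genes <- study$gene_map$gene
  lapply(seq_along(genes), function(j) {
    snps <- strsplit(study$gene_map$snps[j], ",", fixed = TRUE)[[1]]
    fit_gene_weights(study$ref_expression[, j],
                     study$ref_genotypes[, snps, drop = FALSE],
                     gene_id = genes[j], mcmc = mcmc, seed = seed + j)
  })
}

# weights object carrying the generative truth (bypasses training)
.true_study_weights <- function(study) {
  genes <- study$gene_map$gene
  lapply(seq_along(genes), function(j) {
    gam <- study$truth$true_gamma[[j]]
    structure(list(gene_id = genes[j], snp_ids = names(gam),
                   gamma_hat = gam, spike_prob = as.numeric(gam == 0),
                   sigma2_hat = NA_real_, v2_hat = NA_real_, pi_hat = NA_real_),
              class = "phenofm_weights")
  })
}

#' Run a simulation study of the full fine-mapping pipeline
#'
#' For each replicate: simulate a study with known truth, train per-gene
#' expression weights on the reference panel (or use the true weights),
#' impute GReX, run the joint Gibbs sampler in every region, pool omnibus
#' PIPs genome-wide and select genes by BFDR. Records selection counts,
#' false-discovery proportion, ROC AUC of omnibus PIPs against the truth,
#' and the loading-recovery F-score (a loading is called nonzero when its
#' posterior probability of exceeding 0.01 in absolute value is above 0.5).
#'
#' @param scenario simulation scenario (see [sim_config()]).
#' @param m,h2 number of true factors and GReX heritability.
#' @param replicates number of replicates.
#' @param seed master seed; per-replicate seeds are derived from it.
#' @param n1,n2,n_regions,genes_per_region,q,type_mix,causal_per_region
#'   forwarded to [sim_config()].
#' @param alpha BFDR selection level.
#' @param chain a [chain_config()] for the joint sampler (reduced-scale
#'   default: 1000 sweeps, 500 burn-in, thin 2, initial truncation 8).
#' @param expr settings for weight training ([expr_mcmc()]); reduced-scale
#'   default 1200/400/2.
#' @param use_true_weights skip training and impute from the true effects.
#' @param progress print one line per replicate.
#' @return data frame with one row per replicate (`n_selected`, `tp`, `fp`,
#'   `fdp`, `auc`, `f_score`, `m_final`); a `summary` attribute holds means
#'   and Monte-Carlo standard errors.
#' @export
run_simulation_study <- function(scenario = "homogeneous", m = 3, h2 = 0.05,
                                 replicates = 20, seed = 1,
                                 n1 = 250, n2 = 1000, n_regions = 5,
                                 genes_per_region = 10, q = 20,
                                 type_mix = "mixed", causal_per_region = 1.5,
                                 alpha = 0.1,
                                 chain = NULL, expr = NULL,
                                 use_true_weights = FALSE, progress = FALSE) {
  if (is.null(chain))
    chain <- chain_config(iterations = 500, burnin = 250, thin = 2,
                          m_init = 5, m_max = 12, adapt_eps = 0.1)
  if (is.null(expr))
    expr <- expr_mcmc(iterations = 1200, burnin = 400, thin = 2)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max %/% 2, replicates)
  rows <- vector("list", replicates)
  for (i in seq_len(replicates)) {
    res <- tryCatch({
      cfg <- sim_config(scenario = scenario, n1 = n1, n2 = n2,
                        n_regions = n_regions,
                        genes_per_region = genes_per_region, q = q, m = m,
                        h2 = h2, type_mix = type_mix,
                        causal_per_region = causal_per_region,
                        seed = rep_seeds[i])
      study <- simulate_study(cfg)
      weights <- if (use_true_weights) .true_study_weights(study)
                 else .train_study_weights(study, expr, rep_seeds[i])
      grex <- suppressWarnings(impute_grex(study$gwas_genotypes, weights))
      truth_genes <- study$gene_map$gene[study$truth$causal_genes]
      pip_all <- numeric(0)
      fsc <- c()
      for (t in seq_len(n_regions)) {
        genes_t <- study$gene_map$gene[study$gene_map$region == t]
        genes_t <- intersect(genes_t, colnames(grex))
        if (length(genes_t) == 0) next
        dr <- run_chain(grex[, genes_t, drop = FALSE], study$phenotypes$Y,
                        study$phenotypes$types, chain,
                        seed = rep_seeds[i] + 7 * t)
        pips <- compute_pips(dr, align = scenario != "null")
        pip_all <- c(pip_all, setNames(pips$pip_omnibus, genes_t))
        if (scenario != "null" &&
            length(intersect(genes_t, truth_genes)) > 0) {
          al <- align_draws(dr)
          lam_mean <- apply(al$Lambda, c(1, 2), mean)
          supp <- apply(abs(al$Lambda) > 0.01, c(1, 2), mean)
          fsc <- c(fsc, .loading_fscore(lam_mean, supp,
                                        study$truth$true_Lambda))
        }
      }
      sel <- bfdr_select(pip_all, alpha = alpha)
      tp <- length(intersect(sel$selected_genes, truth_genes))
      fp <- length(sel$selected_genes) - tp
      data.frame(replicate = i, scenario = scenario, m = m, h2 = h2,
                 n_selected = length(sel$selected_genes), tp = tp, fp = fp,
                 fdp = if (length(sel$selected_genes) > 0)
                   fp / length(sel$selected_genes) else 0,
                 auc = if (scenario == "null") NA_real_
                       else auc_rank(pip_all,
                                     names(pip_all) %in% truth_genes),
                 top_hit = if (scenario == "null") NA
                           else all(vapply(unique(
                             study$gene_map$region[study$truth$causal_genes]),
                             function(t) {
                               g_t <- study$gene_map$gene[study$gene_map$region == t]
                               g_t <- intersect(g_t, names(pip_all))
                               best <- g_t[which.max(pip_all[g_t])]
                               best %in% truth_genes
                             }, logical(1))),
                 f_score = if (length(fsc) > 0) mean(fsc) else NA_real_,
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      warning("replicate ", i, " failed: ", conditionMessage(e))
      NULL
    })
    rows[[i]] <- res
    if (progress && !is.null(res))
      cat(sprintf("replicate %d: selected=%d tp=%d fp=%d fdp=%.3f\n", i,
                  res$n_selected, res$tp, res$fp, res$fdp))
  }
  out <- do.call(rbind, rows)
  num <- c("n_selected", "tp", "fp", "fdp", "auc", "f_score")
  mu <- colMeans(out[num], na.rm = TRUE)
  se <- vapply(out[num], function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2) NA_real_ else sd(v) / sqrt(length(v))
  }, numeric(1))
  attr(out, "summary") <- list(mean = mu, mc_se = se,
                               n_replicates = nrow(out),
                               n_failed = as.integer(replicates - nrow(out)))
  out
}

# deterministic rolling hash of a config string (manifest fingerprint only)
.fnv_hash <- function(x) {
  h <- 0
  for (b in utf8ToInt(x)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Run the end-to-end fine-mapping pipeline with file handoff
#'
#' Orchestrates simulate -> train-weights -> impute -> regions -> finemap ->
#' report, writing each stage's outputs under `out_dir` and skipping stages
#' whose outputs already exist unless `force = TRUE`. A manifest captures
#' the configuration hash, seed and package version, so artifacts are
#' reproducible from the manifest alone.
#'
#' @param config a list with entries `out_dir`, `seed`, and optional
#'   sublists `sim` (arguments of [sim_config()]), `expr`
#'   ([expr_mcmc()] arguments), `chain` ([chain_config()] arguments),
#'   `region_threshold` (Fisher combined-p threshold, or `NULL` to fine-map
#'   every region) and `alpha` (BFDR level, default 0.1); or the path to a
#'   JSON file holding that list.
#' @param force regenerate all stages.
#' @return invisibly, a list with the selection per analyzed region and the
#'   pooled selection.
#' @export
run_pipeline <- function(config, force = FALSE) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  .assert(!is.null(config$out_dir), "config$out_dir is required")
  out <- config$out_dir
  seed <- config$seed %||% 1
  alpha <- config$alpha %||% 0.1
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  data_dir <- file.path(out, "data")
  stage_log <- list()

  # -- simulate --
  if (force || !file.exists(file.path(data_dir, "phenotypes.tsv"))) {
    cfg <- do.call(sim_config, c(config$sim %||% list(), list(seed = seed)))
    study <- simulate_study(cfg)
    write_study(study, data_dir)
    stage_log$simulate <- "run"
  } else {
    stage_log$simulate <- "skipped"
  }
  Zr <- read_matrix_tsv(file.path(data_dir, "ref_genotypes.tsv"))
  Zg <- read_matrix_tsv(file.path(data_dir, "gwas_genotypes.tsv"))
  expr_mat <- read_matrix_tsv(file.path(data_dir, "ref_expression.tsv"))
  ph <- read_phenotypes(file.path(data_dir, "phenotypes.tsv"))
  gene_map <- read.delim(file.path(data_dir, "gene_map.tsv"),
                         stringsAsFactors = FALSE)

  # -- train weights --
  wpath <- file.path(out, "weights.tsv")
  if (force || !file.exists(wpath)) {
    mc <- do.call(expr_mcmc, config$expr %||%
                    list(iterations = 1200, burnin = 400, thin = 2))
    weights <- lapply(seq_len(nrow(gene_map)), function(j) {
      snps <- strsplit(gene_map$snps[j], ",", fixed = TRUE)[[1]]
      fit_gene_weights(expr_mat[, j], Zr[, snps, drop = FALSE],
                       gene_id = gene_map$gene[j], mcmc = mc, seed = seed + j)
    })
    write_weights(weights, wpath)
    stage_log$weights <- "run"
  } else {
    weights <- read_weights(wpath)
    stage_log$weights <- "skipped"
  }

  # -- impute GReX --
  gpath <- file.path(out, "grex.tsv")
  if (force || !file.exists(gpath)) {
    grex <- suppressWarnings(impute_grex(Zg, weights))
    write_matrix_tsv(grex, gpath)
    stage_log$grex <- "run"
  } else {
    grex <- read_matrix_tsv(gpath)
    stage_log$grex <- "skipped"
  }

  # -- region screening --
  regions <- sort(unique(gene_map$region))
  if (!is.null(config$region_threshold)) {
    tw <- twas_scan(grex, ph$Y, ph$types)
    fisher_p <- apply(tw, 1, fisher_combine)
    keep <- gene_map$region[match(rownames(tw)[fisher_p <
                                                 config$region_threshold],
                                  gene_map$gene)]
    regions <- sort(unique(keep))
    write.table(data.frame(gene = rownames(tw), fisher_p = fisher_p),
                file.path(out, "fisher.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    stage_log$regions <- paste(length(regions), "selected")
  } else {
    stage_log$regions <- "all"
  }

  # -- fine mapping per region + report --
  chain <- do.call(chain_config, config$chain %||%
                     list(iterations = 1000, burnin = 500, thin = 2,
                          m_init = 8))
  pip_all <- numeric(0)
  per_region <- list()
  for (t in regions) {
    genes_t <- intersect(gene_map$gene[gene_map$region == t], colnames(grex))
    if (length(genes_t) == 0) next
    dr <- run_chain(grex[, genes_t, drop = FALSE], ph$Y, ph$types, chain,
                    seed = seed + 7 * t)
    pips <- compute_pips(dr)
    sel <- bfdr_select(pips, alpha = alpha)
    report(sel, dr, file.path(out, paste0("region_", t)))
    per_region[[as.character(t)]] <- sel
    pip_all <- c(pip_all, setNames(pips$pip_omnibus, genes_t))
  }
  pooled <- bfdr_select(pip_all, alpha = alpha)
  jsonlite::write_json(
    list(selected_genes = pooled$selected_genes,
         threshold = pooled$threshold, bfdr = pooled$bfdr_at_threshold,
         pip = as.list(pooled$pip_omnibus)),
    file.path(out, "selection.json"), auto_unbox = TRUE, digits = NA)

  version <- tryCatch(as.character(utils::packageVersion("phenofm")),
                      error = function(e) "unknown")
  hashed <- config[setdiff(names(config), "out_dir")] # path-independent
  hashed <- hashed[order(names(hashed))]
  manifest <- list(config_hash = .fnv_hash(jsonlite::toJSON(hashed,
                                                            auto_unbox = TRUE)),
                   seed = seed, version = version,
                   regions_analyzed = regions)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(per_region = per_region, pooled = pooled,
                 manifest = manifest, stages = stage_log))
}
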