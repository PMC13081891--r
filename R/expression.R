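#' MCMC settings for per-gene expression model training
#'
#' @param iterations,burnin,thin chain length controls.
#' @param fix_pi,fix_v2,fix_sigma2 optionally freeze a hyperparameter at a
#'   value (used for conjugate-oracle validation); `NA` means sampled.
#' @param prior_v,prior_sigma `c(shape, rate)` of the inverse-gamma priors on
#'   the slab scale `v2` and residual variance `sigma2`; `c(0, 0)` is the
#'   Jeffreys limit `1/v2`, `1/sigma2`.
#' @param store_draws keep thinned `gamma` draws on the returned object.
#' @return a list of settings for [fit_gene_weights()].
#' @export
expr_mcmc <- function(iterations = 4000, burnin = 2000, thin = 2,
                      fix_pi = NA, fix_v2 = NA, fix_sigma2 = NA,
                      prior_v = c(0, 0), prior_sigma = c(0, 0),
                      store_draws = FALSE) {
  .assert(iterations > burnin && burnin >= 0 && thin >= 1, "invalid chain lengths")
  list(iterations = as.integer(iterations), burnin = as.integer(burnin),
       thin = as.integer(thin), fix_pi = fix_pi, fix_v2 = fix_v2,
       fix_sigma2 = fix_sigma2, prior_v = prior_v, prior_sigma = prior_sigma,
       store_draws = isTRUE(store_draws))
}

#' Train a per-gene Bayesian sparse expression model
#'
#' Fits `x = Z gamma + eps` on a reference panel by Gibbs sampling under a
#' spike-and-slab prior
#' `gamma_d ~ I_d delta_0 + (1 - I_d) N(0, v2 sigma2)`, `I_d ~ Ber(pi)`,
#' with `pi ~ Unif(0, 1)` and Jeffreys priors on `v2` and `sigma2`. The
#' indicator `I_d = 1` selects the spike (a zero effect); the reported
#' `spike_prob` is the posterior probability of that event. Effects used for
#' imputation are posterior means.
#'
#' @param x expression vector (length `n1`).
#' @param Z_ref `n1 x g` genotype matrix; standardized internally if needed.
#'   Zero-variance columns are dropped with a warning.
#' @param gene_id identifier carried to the output.
#' @param mcmc an [expr_mcmc()] settings list.
#' @param seed optional seed.
#' @return a `phenofm_weights` object: `gene_id`, `snp_ids`, `gamma_hat`,
#'   `spike_prob`, `sigma2_hat`, `v2_hat`, `pi_hat` (+ `draws` if requested).
#' @export
fit_gene_weights <- function(x, Z_ref, gene_id = "gene", mcmc = expr_mcmc(),
                             seed = NULL) {
  .assert(is.numeric(x) && all(is.finite(x)), "'x' must be finite numeric")
  Z_ref <- as.matrix(Z_ref)
  .assert(length(x) == nrow(Z_ref), "length(x) must match nrow(Z_ref)")
  .assert(length(x) >= 3, "need at least 3 reference individuals")
  if (is.null(colnames(Z_ref)))
    colnames(Z_ref) <- paste0("snp", seq_len(ncol(Z_ref)))
  sdv <- apply(Z_ref, 2, sd)
  if (any(sdv == 0)) {
    warning("dropping ", sum(sdv == 0), " zero-variance SNP column(s) for ",
            gene_id)
    Z_ref <- Z_ref[, sdv > 0, drop = FALSE]
  }
  .assert(ncol(Z_ref) >= 1, "no usable SNP columns")
  if (!.is_standardized(Z_ref)) Z_ref <- .standardize_cols(Z_ref)
  if (!is.null(seed)) set.seed(seed)
  fit <- .expr_gibbs(x, Z_ref, mcmc$iterations, mcmc$burnin, mcmc$thin,
                     as.numeric(mcmc$fix_pi), as.numeric(mcmc$fix_v2),
                     as.numeric(mcmc$fix_sigma2),
                     mcmc$prior_v[1], mcmc$prior_v[2],
                     mcmc$prior_sigma[1], mcmc$prior_sigma[2])
  out <- structure(list(
    gene_id = gene_id, snp_ids = colnames(Z_ref),
    gamma_hat = setNames(colMeans(fit$gamma), colnames(Z_ref)),
    spike_prob = setNames(colMeans(fit$spike), colnames(Z_ref)),
    sigma2_hat = mean(fit$sigma2), v2_hat = mean(fit$v2),
    pi_hat = mean(fit$pi)), class = "phenofm_weights")
  if (mcmc$store_draws) out$draws <- fit
  out
}

#' Impute genetically regulated expression into a GWAS cohort
#'
#' For each trained gene, forms `xhat_j = Z_j gamma_hat_j` from the GWAS
#' genotypes (columns matched by SNP identifier) and standardizes the result.
#' Genes whose posterior-mean effects are all zero are dropped with a warning.
#'
#' @param Z_gwas standardized `n2 x g` GWAS genotype matrix with SNP column
#'   names.
#' @param weights a `phenofm_weights` object or list of them.
#' @return standardized `n2 x p` GReX matrix (gene ids as column names);
#'   attribute `dropped` lists excluded genes.
#' @export
impute_grex <- function(Z_gwas, weights) {
  if (inherits(weights, "phenofm_weights")) weights <- list(weights)
  .assert(length(weights) > 0, "no weights supplied")
  .assert(!is.null(colnames(Z_gwas)), "Z_gwas must have SNP column names")
  cols <- list(); dropped <- character(0)
  for (w in weights) {
    miss <- setdiff(w$snp_ids, colnames(Z_gwas))
    if (length(miss) > 0)
      stop("gene ", w$gene_id, ": SNP(s) missing from GWAS genotypes: ",
           paste(miss, collapse = ", "), call. = FALSE)
    if (all(w$gamma_hat == 0)) {
      dropped <- c(dropped, w$gene_id)
      next
    }
    cols[[w$gene_id]] <-
      as.vector(Z_gwas[, w$snp_ids, drop = FALSE] %*% w$gamma_hat)
  }
  if (length(dropped) > 0)
    warning("dropped gene(s) with all-zero weights: ",
            paste(dropped, collapse = ", "))
  .assert(length(cols) > 0, "all genes had zero weights; nothing to impute")
  out <- .standardize_cols(do.call(cbind, cols))
  colnames(out) <- names(cols)
  attr(out, "dropped") <- dropped
  attr(out, "constant_columns") <- NULL
  out
}

#' Read and write gene weight tables
#'
#' The TSV dialect has columns `gene`, `rsid`, `weight` and optionally
#' `spike_prob`; unrecognized columns are preserved on a round trip.
#' Duplicated `(gene, rsid)` rows are a format error.
#'
#' @param weights list of `phenofm_weights` (or a single one).
#' @param path file path.
#' @return `read_weights` returns a list of `phenofm_weights`;
#'   `write_weights` returns `path` invisibly.
#' @export
write_weights <- function(weights, path) {
  if (inherits(weights, "phenofm_weights")) weights <- list(weights)
  rows <- lapply(weights, function(w) {
    df <- data.frame(gene = w$gene_id, rsid = w$snp_ids,
                     weight = unname(w$gamma_hat),
                     stringsAsFactors = FALSE)
    if (!is.null(w$spike_prob)) df$spike_prob <- unname(w$spike_prob)
    extra <- attr(w, "extra")
    if (!is.null(extra)) df <- cbind(df, extra)
    df
  })
  tab <- do.call(rbind, rows)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_weights
#' @export
read_weights <- function(path) {
  first <- readLines(path, n = 1)
  if (length(first) == 0) return(list())
  hdr <- strsplit(first, "\t", fixed = TRUE)[[1]]
  if (!all(c("gene", "rsid", "weight") %in% hdr))
    stop("malformed weight file header (line 1): need gene, rsid, weight",
         call. = FALSE)
  tab <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (nrow(tab) == 0) return(list())
  key <- paste(tab$gene, tab$rsid)
  if (anyDuplicated(key)) {
    line <- which(duplicated(key))[1] + 1
    stop("duplicated (gene, rsid) entry at line ", line, call. = FALSE)
  }
  known <- c("gene", "rsid", "weight", "spike_prob")
  lapply(split(tab, factor(tab$gene, levels = unique(tab$gene))), function(d) {
    w <- structure(list(
      gene_id = d$gene[1], snp_ids = d$rsid,
      gamma_hat = setNames(d$weight, d$rsid),
      spike_prob = if ("spike_prob" %in% names(d))
        setNames(d$spike_prob, d$rsid) else NULL,
      sigma2_hat = NA_real_, v2_hat = NA_real_, pi_hat = NA_real_),
      class = "phenofm_weights")
    extra_cols <- setdiff(names(d), known)
    if (length(extra_cols) > 0) attr(w, "extra") <- d[, extra_cols, drop = FALSE]
    w
  })
}

#' @export
print.phenofm_weights <- function(x, ...) {
  cat("Gene weights for ", x$gene_id, ": ", length(x$snp_ids), " SNPs, ",
      sum(x$gamma_hat != 0), " nonzero posterior-mean effects\n", sep = "")
  invisible(x)
}
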