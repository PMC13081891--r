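#' Single-gene association test between GReX and one phenotype
#'
#' Wald p-value for the GReX term in a linear model (continuous outcome),
#' logistic regression (binary) or negative-binomial regression (count),
#' with optional additive covariates. Used to build the univariate TWAS
#' p-value table that feeds region screening.
#'
#' @param grex_col standardized imputed-expression vector for one gene.
#' @param y outcome vector.
#' @param outcome_type `"continuous"`, `"binary"` or `"count"`.
#' @param covariates optional numeric matrix of additive covariates.
#' @return a p-value in (0, 1], or `NA` with a warning when the model fails
#'   to converge (e.g. separation).
#' @export
univariate_twas <- function(grex_col, y,
                            outcome_type = c("continuous", "binary", "count"),
                            covariates = NULL) {
  outcome_type <- match.arg(outcome_type)
  .assert(length(grex_col) == length(y), "length mismatch")
  dat <- data.frame(y = y, g = grex_col)
  form <- y ~ g
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    .assert(nrow(covariates) == length(y), "covariate rows must match y")
    .assert(qr(cbind(1, covariates))$rank == ncol(covariates) + 1,
            "covariates must be full rank")
    colnames(covariates) <- paste0("c", seq_len(ncol(covariates)))
    dat <- cbind(dat, covariates)
    form <- stats::reformulate(c("g", colnames(covariates)), response = "y")
  }
  p <- tryCatch({
    fit <- switch(outcome_type,
      continuous = lm(form, data = dat),
      binary = suppressWarnings(glm(form, family = binomial(), data = dat)),
      count = suppressWarnings(MASS::glm.nb(form, data = dat)))
    co <- summary(fit)$coefficients
    pv <- co["g", 4]
    if (outcome_type != "continuous" && !is.null(fit$converged) &&
        !fit$converged) NA_real_ else pv
  }, error = function(e) NA_real_)
  if (is.na(p)) warning("association model did not converge; p = NA")
  p
}

#' Univariate TWAS p-value matrix over all genes and phenotypes
#'
#' @param grex standardized GReX matrix (`n x p`, gene ids as column names).
#' @param Y phenotype matrix (`n x q`).
#' @param types per-phenotype outcome types.
#' @param covariates optional covariate matrix passed to every test.
#' @return gene-by-phenotype matrix of p-values.
#' @export
twas_scan <- function(grex, Y, types, covariates = NULL) {
  .assert(ncol(Y) == length(types), "one type per phenotype required")
  out <- matrix(NA_real_, ncol(grex), ncol(Y),
                dimnames = list(colnames(grex), colnames(Y)))
  for (j in seq_len(ncol(grex)))
    for (k in seq_len(ncol(Y)))
      out[j, k] <- suppressWarnings(
        univariate_twas(grex[, j], Y[, k], types[k], covariates))
  out
}

#' Combine p-values across phenotypes with Fisher's method
#'
#' The statistic `-2 sum(log p)` is referred to a chi-square distribution
#' with `2q` degrees of freedom. With correlated phenotypes the combined
#' value is a screening score rather than a calibrated test; it is used here
#' to rank regions for fine mapping.
#'
#' @param pvals vector of p-values in (0, 1].
#' @return the upper-tail combined p-value.
#' @examples
#' fisher_combine(c(0.5, 0.5)) # 0.5966 (chi-square_4 at 2.7726)
#' @export
fisher_combine <- function(pvals) {
  pvals <- pvals[!is.na(pvals)]
  .assert(length(pvals) >= 1, "no p-values to combine")
  .assert(all(pvals > 0 & pvals <= 1), "p-values must lie in (0, 1]")
  pchisq(-2 * sum(log(pvals)), df = 2 * length(pvals), lower.tail = FALSE)
}

#' Select LD-block regions of interest from univariate TWAS evidence
#'
#' Combines each gene's p-values across phenotypes with Fisher's method and
#' selects every block containing at least one gene whose combined p-value
#' falls below `threshold`.
#'
#' @param twas gene-by-phenotype p-value matrix (genes as rownames).
#' @param blocks data frame of LD blocks: `block_id`, `chrom`, `start`,
#'   `end` (0-based half-open, BED convention).
#' @param gene_to_block named character vector mapping every gene to a block
#'   id.
#' @param threshold combined-p selection threshold (default `1e-8`).
#' @return list with `selected_blocks`, per-gene `fisher_p`, and
#'   `genes_by_block` (gene ids of every selected block, for fine mapping).
#' @export
select_regions <- function(twas, blocks, gene_to_block, threshold = 1e-8) {
  genes <- rownames(twas)
  .assert(!is.null(genes), "twas matrix must have gene rownames")
  unmapped <- setdiff(genes, names(gene_to_block))
  if (length(unmapped) > 0)
    stop("gene(s) not mapped to any block: ", paste(unmapped, collapse = ", "),
         call. = FALSE)
  .assert(all(gene_to_block[genes] %in% blocks$block_id),
          "gene mapped to unknown block")
  fisher_p <- apply(twas, 1, fisher_combine)
  hit_blocks <- unique(gene_to_block[genes[fisher_p < threshold]])
  sel <- blocks[blocks$block_id %in% hit_blocks, , drop = FALSE]
  genes_by_block <- lapply(setNames(sel$block_id, sel$block_id), function(bid)
    genes[gene_to_block[genes] == bid])
  list(selected_blocks = sel, fisher_p = fisher_p,
       genes_by_block = genes_by_block, threshold = threshold)
}

#' Read an LD-block BED file
#'
#' Three or four tab-separated columns (`chrom`, `start`, `end`, optional
#' `block_id`), 0-based half-open intervals; a `block_id` is generated when
#' absent. Overlapping blocks within a chromosome are an error.
#'
#' @param path BED file path.
#' @return data frame with `block_id`, `chrom`, `start`, `end`.
#' @export
read_blocks <- function(path) {
  tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                    comment.char = "#")
  .assert(ncol(tab) >= 3, "BED file needs at least 3 columns")
  names(tab)[1:3] <- c("chrom", "start", "end")
  tab$block_id <- if (ncol(tab) >= 4) as.character(tab[[4]])
                  else paste0(tab$chrom, ":", tab$start, "-", tab$end)
  .assert(all(tab$end > tab$start), "block end must exceed start")
  for (ch in unique(tab$chrom)) {
    d <- tab[tab$chrom == ch, , drop = FALSE]
    d <- d[order(d$start), , drop = FALSE]
    if (nrow(d) > 1) .assert(all(d$start[-1] >= d$end[-nrow(d)]),
                             "overlapping blocks within a chromosome")
  }
  tab[, c("block_id", "chrom", "start", "end")]
}
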