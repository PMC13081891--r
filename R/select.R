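#' Posterior inclusion probabilities from stored draws
#'
#' Factor-specific PIPs `P(beta_jl != 0 | data)` are draw frequencies of a
#' nonzero effect computed on aligned draws (see [align_draws()]); the
#' omnibus PIP `P(U_l beta_jl != 0 | data)` is the frequency with which the
#' gene is active on at least one factor, computed on raw draws since the
#' union event is invariant to factor relabeling.
#'
#' @param draws a `phenofm_draws` object with at least 100 stored sweeps.
#' @param align align draws before computing factor-specific PIPs.
#' @return a `phenofm_pips` list: `pip_factor` (`p x m`), `pip_omnibus`
#'   (length `p`), `n_draws`, `gene_ids`.
#' @export
compute_pips <- function(draws, align = TRUE) {
  .assert(inherits(draws, "phenofm_draws"), "'draws' must come from run_chain()")
  .assert(draws$n_draws > 0, "no stored draws")
  if (draws$n_draws < 100)
    warning("fewer than 100 stored draws; PIPs will be noisy")
  active_raw <- draws$B != 0 # p x m x S
  pip_omnibus <- apply(apply(active_raw, c(1, 3), any), 1, mean)
  if (align) draws <- align_draws(draws)
  pip_factor <- apply(draws$B != 0, c(1, 2), mean)
  structure(list(pip_factor = pip_factor, pip_omnibus = pip_omnibus,
                 n_draws = draws$n_draws, gene_ids = draws$gene_ids),
            class = "phenofm_pips")
}

.bfdr_scan <- function(pips, alpha) {
  stopifnot(all(pips >= 0 & pips <= 1))
  thresholds <- sort(unique(pips), decreasing = TRUE)
  best <- NULL
  for (z in thresholds) {
    sel <- which(pips >= z)
    bfdr <- mean(1 - pips[sel])
    if (bfdr <= alpha) best <- list(threshold = z, bfdr = bfdr, selected = sel)
    else break # BFDR over {PIP >= z} is non-increasing in z
  }
  if (is.null(best)) list(threshold = NA_real_, bfdr = NA_real_,
                          selected = integer(0))
  else best
}

#' Select genes by Bayesian false discovery rate control
#'
#' For a candidate threshold `z` the selected set is `{j : PIP_j >= z}` and
#' its Bayesian FDR is the mean of `1 - PIP` over the set. The reported
#' threshold is the smallest `z` (hence the largest selection) with
#' `BFDR(z) <= alpha`. When a PIP table is supplied, factor-specific
#' selections are additionally performed per factor (each factor gets its
#' own threshold) and reported as the selected genes' target factors.
#'
#' @param pips numeric vector of omnibus PIPs, or a `phenofm_pips` object.
#' @param alpha nominal BFDR level; 0.1 is the simulation-evaluation default
#'   and 0.15 a common choice for applications.
#' @return a `phenofm_selection` list: `selected_genes`, `threshold`,
#'   `bfdr_at_threshold`, `alpha`, and (when available) `factor_targets`
#'   plus the per-factor thresholds.
#' @examples
#' bfdr_select(c(0.99, 0.95, 0.60, 0.10), alpha = 0.05) # selects the top two
#' @export
bfdr_select <- function(pips, alpha = 0.1) {
  .assert(alpha > 0 && alpha < 1, "'alpha' must be in (0, 1)")
  pip_tab <- NULL
  if (inherits(pips, "phenofm_pips")) {
    pip_tab <- pips
    pips <- pip_tab$pip_omnibus
  }
  .assert(all(pips >= 0 & pips <= 1), "PIPs must lie in [0, 1]")
  gene_ids <- if (!is.null(pip_tab)) pip_tab$gene_ids
              else names(pips) %||% as.character(seq_along(pips))
  sc <- .bfdr_scan(pips, alpha)
  out <- list(selected_genes = gene_ids[sc$selected],
              selected_idx = sc$selected, threshold = sc$threshold,
              bfdr_at_threshold = sc$bfdr, alpha = alpha,
              pip_omnibus = setNames(pips, gene_ids))
  if (!is.null(pip_tab)) {
    m <- ncol(pip_tab$pip_factor)
    fac_sel <- lapply(seq_len(m), function(l)
      .bfdr_scan(pip_tab$pip_factor[, l], alpha))
    out$factor_thresholds <- vapply(fac_sel, `[[`, numeric(1), "threshold")
    out$factor_targets <- lapply(sc$selected, function(j)
      which(vapply(seq_len(m), function(l) j %in% fac_sel[[l]]$selected,
                   logical(1))))
    names(out$factor_targets) <- gene_ids[sc$selected]
    out$pip_factor <- pip_tab$pip_factor
  }
  structure(out, class = "phenofm_selection")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write fine-mapping reports
#'
#' Writes a gene table (omnibus and per-factor PIPs, selection flag and the
#' BFDR at the selection threshold), one phenotype-loading table per factor
#' involved in the selection (rows sorted by absolute posterior-mean
#' loading), and a JSON manifest. Output is deterministic given the draws.
#'
#' @param selection a `phenofm_selection` from [bfdr_select()].
#' @param draws the `phenofm_draws` the selection was computed from.
#' @param out_dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
report <- function(selection, draws, out_dir) {
  .assert(inherits(selection, "phenofm_selection"), "invalid selection")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  aligned <- align_draws(draws)
  lam_mean <- apply(aligned$Lambda, c(1, 2), mean)
  m <- ncol(lam_mean)
  gene_tab <- data.frame(gene = names(selection$pip_omnibus),
                         pip_omnibus = unname(selection$pip_omnibus),
                         selected = names(selection$pip_omnibus) %in%
                           selection$selected_genes,
                         stringsAsFactors = FALSE)
  if (!is.null(selection$pip_factor))
    for (l in seq_len(ncol(selection$pip_factor)))
      gene_tab[[paste0("pip_factor", l)]] <- selection$pip_factor[, l]
  gene_tab$bfdr_threshold <- selection$threshold
  gene_tab$bfdr_at_threshold <- selection$bfdr_at_threshold
  gene_path <- file.path(out_dir, "genes.tsv")
  write.table(gene_tab, gene_path, sep = "\t", quote = FALSE, row.names = FALSE)

  loading_paths <- character(0)
  involved <- sort(unique(unlist(selection$factor_targets %||% seq_len(m))))
  for (l in involved) {
    tab <- data.frame(phenotype = draws$phenotype_ids %||%
                        paste0("pheno_", seq_len(nrow(lam_mean))),
                      loading = lam_mean[, l], stringsAsFactors = FALSE)
    tab <- tab[order(-abs(tab$loading)), , drop = FALSE]
    pth <- file.path(out_dir, paste0("loadings_factor", l, ".tsv"))
    write.table(tab, pth, sep = "\t", quote = FALSE, row.names = FALSE)
    loading_paths <- c(loading_paths, pth)
  }
  manifest <- list(alpha = selection$alpha,
                   threshold = selection$threshold,
                   bfdr_at_threshold = selection$bfdr_at_threshold,
                   n_selected = length(selection$selected_genes),
                   selected_genes = selection$selected_genes,
                   n_draws = draws$n_draws, m = m,
                   files = c("genes.tsv", basename(loading_paths)))
  man_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(gene_path, loading_paths, man_path))
}

#' @export
print.phenofm_selection <- function(x, ...) {
  cat("BFDR selection at alpha = ", x$alpha, ": ",
      length(x$selected_genes), " gene(s)", sep = "")
  if (length(x$selected_genes) > 0)
    cat(" [", paste(x$selected_genes, collapse = ", "), "] at PIP >= ",
        signif(x$threshold, 3), " (BFDR ", signif(x$bfdr_at_threshold, 3),
        ")", sep = "")
  cat("\n")
  invisible(x)
}
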