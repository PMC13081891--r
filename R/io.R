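#' Read and write sample-by-feature matrices as TSV
#'
#' Plain tab-separated tables with a header row and the sample identifier in
#' the first column.
#'
#' @param M numeric matrix (feature names as column names).
#' @param path file path.
#' @param sample_ids optional sample identifiers (default `s1, s2, ...`).
#' @return `read_matrix_tsv` returns a numeric matrix with sample ids as
#'   rownames.
#' @export
write_matrix_tsv <- function(M, path, sample_ids = NULL) {
  if (is.null(sample_ids)) sample_ids <- rownames(M) %||% paste0("s", seq_len(nrow(M)))
  df <- data.frame(sample = sample_ids, M, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  M <- as.matrix(df[, -1, drop = FALSE])
  rownames(M) <- df[[1]]
  storage.mode(M) <- "double"
  M
}

#' Read and write phenotype tables with per-column type tags
#'
#' The TSV carries a `#type` line immediately after the header naming each
#' column's outcome type (`continuous`, `binary`, `count`).
#'
#' @param Y phenotype matrix.
#' @param types per-column types.
#' @param path file path.
#' @return `read_phenotypes` returns `list(Y, types)`.
#' @export
write_phenotypes <- function(Y, types, path) {
  .assert(ncol(Y) == length(types), "one type per column required")
  ids <- rownames(Y) %||% paste0("s", seq_len(nrow(Y)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("sample", colnames(Y) %||%
                       paste0("pheno_", seq_len(ncol(Y)))), collapse = "\t"), con)
  writeLines(paste(c("#type", types), collapse = "\t"), con)
  write.table(data.frame(ids, Y, check.names = FALSE), con, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  lines <- readLines(path, n = 2)
  .assert(length(lines) == 2 && startsWith(lines[2], "#type"),
          "phenotype file must carry a '#type' tag line after the header")
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  types <- strsplit(lines[2], "\t", fixed = TRUE)[[1]][-1]
  df <- read.delim(path, skip = 2, header = FALSE, stringsAsFactors = FALSE)
  names(df) <- header
  Y <- as.matrix(df[, -1, drop = FALSE])
  rownames(Y) <- df[[1]]
  storage.mode(Y) <- "double"
  .assert(length(types) == ncol(Y), "type line does not match columns")
  list(Y = Y, types = types)
}

#' Write a synthetic study to a directory of plain-text files
#'
#' Genotypes, expression and phenotypes as TSV; the gene map as TSV; the
#' generative truth as a JSON sidecar.
#'
#' @param study a `phenofm_study` from [simulate_study()].
#' @param dir output directory.
#' @return invisibly, the directory.
#' @export
write_study <- function(study, dir) {
  .assert(inherits(study, "phenofm_study"), "'study' must come from simulate_study()")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_matrix_tsv(study$ref_genotypes, file.path(dir, "ref_genotypes.tsv"))
  write_matrix_tsv(study$gwas_genotypes, file.path(dir, "gwas_genotypes.tsv"))
  write_matrix_tsv(study$ref_expression, file.path(dir, "ref_expression.tsv"))
  write_phenotypes(study$phenotypes$Y, study$phenotypes$types,
                   file.path(dir, "phenotypes.tsv"))
  write.table(study$gene_map, file.path(dir, "gene_map.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  truth <- study$truth
  truth$true_gamma <- lapply(truth$true_gamma, as.list)
  jsonlite::write_json(
    c(truth, list(config = unclass(study$config))),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
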