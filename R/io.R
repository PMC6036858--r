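## Labeled-matrix I/O and fit export.  File dialect: header row of column
## labels, first column of row labels, tab-separated (".csv" switches to
## commas), numeric values printed with 10 significant digits.

.sep_for <- function(path) if (grepl("\\.csv$", path, TRUE)) "," else "\t"

#' Read a labeled numeric matrix from delimited text
#'
#' Expects a header row of column labels and a first column of row labels;
#' the delimiter is inferred from the extension (`.csv` comma, otherwise
#' tab).  Missing or non-numeric cells are an error naming the offending
#' coordinates.
#'
#' @param path file path.
#' @param orientation `"samples"` if rows are samples (the native layout),
#'   `"features"` to transpose a features-in-rows file on read.
#' @return numeric matrix with dimnames.
#' @export
read_matrix <- function(path, orientation = c("samples", "features")) {
  orientation <- match.arg(orientation)
  df <- utils::read.table(path, header = TRUE, sep = .sep_for(path),
                          row.names = 1L, check.names = FALSE,
                          comment.char = "", colClasses = "character")
  mat <- suppressWarnings(
    matrix(as.numeric(as.matrix(df)), nrow(df), ncol(df),
           dimnames = list(rownames(df), colnames(df))))
  bad <- which(is.na(mat) | !is.finite(mat), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("missing or non-numeric value at row '%s', column '%s' in %s",
                 rownames(mat)[bad[1L, 1L]], colnames(mat)[bad[1L, 2L]],
                 path))
  if (orientation == "features") mat <- t(mat)
  mat
}

#' Write a labeled numeric matrix as delimited text
#'
#' Inverse of [read_matrix()]: header row, row-label column, values with 10
#' significant digits.
#'
#' @param mat numeric matrix; missing dimnames are generated.
#' @param path output path; `.csv` selects commas, anything else tabs.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(mat, path) {
  sep <- .sep_for(path)
  rn <- rownames(mat) %||% paste0("r", seq_len(nrow(mat)))
  cn <- colnames(mat) %||% paste0("c", seq_len(ncol(mat)))
  lines <- c(paste(c("id", cn), collapse = sep),
             vapply(seq_len(nrow(mat)), function(i)
               paste(c(rn[i], sprintf("%.10g", mat[i, ])), collapse = sep),
               ""))
  writeLines(lines, path)
  invisible(path)
}

#' Write the nonzero links of a precision matrix as an edge list
#'
#' One row per unordered gene pair with a nonzero off-diagonal entry,
#' columns `gene_a`, `gene_b`, `k_value`, tab-separated.
#'
#' @param K_hat symmetric estimated precision matrix.
#' @param gene_ids labels; defaults to rownames of `K_hat`.
#' @param path output path.
#' @return number of edges written, invisibly.
#' @export
write_network <- function(K_hat, gene_ids = NULL, path) {
  m <- nrow(K_hat)
  gene_ids <- gene_ids %||% rownames(K_hat) %||% paste0("gene", seq_len(m))
  idx <- which(upper.tri(K_hat) & K_hat != 0, arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  lines <- c("gene_a\tgene_b\tk_value",
             if (nrow(idx)) vapply(seq_len(nrow(idx)), function(i)
               sprintf("%s\t%s\t%.10g", gene_ids[idx[i, 1L]],
                       gene_ids[idx[i, 2L]], K_hat[idx[i, 1L], idx[i, 2L]]),
               ""))
  writeLines(lines, path)
  invisible(nrow(idx))
}

#' Export a fitted model to files
#'
#' Writes the estimated precision matrix and coefficient matrix as labeled
#' matrices, the network edge list, the selection trace, and a JSON summary
#' with a provenance block (package version, seed, configuration).
#'
#' @param fit a `jmccm_fit` from [jmccm()].
#' @param prefix output path prefix.
#' @param seed seed recorded in the provenance block.
#' @return named character vector of the written paths, invisibly.
#' @export
write_fit <- function(fit, prefix, seed = NA) {
  m <- fit$chol$m
  gene_ids <- fit$gene_ids %||% paste0("gene", seq_len(m))
  snp_ids <- fit$snp_ids %||% paste0("snp", seq_len(max(c(0L, unlist(fit$G)))))
  paths <- c(K = paste0(prefix, "_K.tsv"),
             beta = paste0(prefix, "_beta.tsv"),
             edges = paste0(prefix, "_edges.tsv"),
             trace = paste0(prefix, "_trace.tsv"),
             summary = paste0(prefix, "_summary.json"))
  K <- fit$K_hat
  dimnames(K) <- list(gene_ids, gene_ids)
  write_matrix(K, paths[["K"]])
  B <- matrix(0, length(snp_ids) + 1L, m,
              dimnames = list(c("(Intercept)", snp_ids), gene_ids))
  for (j in seq_len(m)) B[c(1L, fit$G[[j]] + 1L), j] <- fit$mean$beta[[j]]
  write_matrix(B, paths[["beta"]])
  n_edges <- write_network(K, gene_ids, paths[["edges"]])
  tr <- fit$trace
  if (is.null(tr))
    tr <- data.frame(stage = character(0), term = character(0),
                     statistic = numeric(0), criterion = numeric(0),
                     accepted = logical(0))
  utils::write.table(tr, paths[["trace"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  summary <- list(
    m = m, p = length(snp_ids),
    loglik = fit$loglik, bic = fit$bic %||% NA,
    n_active_beta = sum(vapply(fit$G, length, 1L)),
    n_active_phi = sum(fit$active),
    n_edges = n_edges,
    converged = fit$converged,
    provenance = list(package = "jmccm",
                      version = as.character(utils::packageVersion("jmccm")),
                      seed = seed, date = format(Sys.time(), "%Y-%m-%d")))
  jsonlite::write_json(summary, paths[["summary"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
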