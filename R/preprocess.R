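#' Log2-transform an expression matrix
#'
#' @param expr Genes x samples numeric matrix of strictly positive raw
#'   intensities.
#' @return The elementwise log2 matrix, tagged with stage "log2".
#' @export
#' @examples
#' log2_transform(matrix(c(1, 8), 1, 2, dimnames = list("g1", c("a", "b"))))
log2_transform <- function(expr) {
  bad <- which(expr <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-positive value at gene '%s', sample '%s'",
                 rownames(expr)[bad[1, 1]], colnames(expr)[bad[1, 2]]),
         call. = FALSE)
  }
  out <- log2(expr)
  attr(out, "stage") <- "log2"
  out
}

#' Quantile-normalize the columns of an expression matrix
#'
#' Classic quantile normalization: within each column, the value of rank r
#' is replaced by the mean over columns of the rank-r order statistics;
#' ties receive the mean of their tied rank-means. Delegates to
#' \code{limma::normalizeQuantiles(ties = TRUE)}. After normalization every
#' column carries the identical multiset of values (up to tie handling),
#' and the operation is idempotent.
#'
#' @param expr Genes x samples numeric matrix, no missing values.
#' @return Normalized matrix, tagged with stage "normalized". A
#'   single-column matrix is returned unchanged with a warning.
#' @export
quantile_normalize <- function(expr) {
  if (anyNA(expr))
    stop("missing values are not supported", call. = FALSE)
  if (ncol(expr) < 2) {
    warning("only one sample; quantile normalization skipped")
    return(expr)
  }
  out <- limma::normalizeQuantiles(expr, ties = TRUE)
  dimnames(out) <- dimnames(expr)
  attr(out, "stage") <- "normalized"
  out
}

#' Collapse probe-level rows to one gene-level row by arithmetic mean
#'
#' @param expr Probes x samples numeric matrix.
#' @param probe_to_gene Named character vector mapping probe id to gene
#'   id. Probes absent from the mapping are dropped with a warning.
#' @return Genes x samples matrix, rows in lexicographic gene order.
#' @export
collapse_probes_mean <- function(expr, probe_to_gene) {
  if (length(probe_to_gene) == 0)
    stop("empty probe-to-gene mapping", call. = FALSE)
  mapped <- rownames(expr) %in% names(probe_to_gene)
  if (!all(mapped)) {
    warning(sum(!mapped), " unmapped probe(s) dropped")
    expr <- expr[mapped, , drop = FALSE]
  }
  if (nrow(expr) == 0)
    stop("no probes left after dropping unmapped ones", call. = FALSE)
  genes <- probe_to_gene[rownames(expr)]
  sums <- rowsum(expr, group = genes)
  counts <- as.vector(table(genes)[rownames(sums)])
  out <- sums / counts
  out <- out[order(rownames(out)), , drop = FALSE]
  attr(out, "stage") <- attr(expr, "stage")
  out
}

#' Keep the n most variable genes
#'
#' Ranks genes by sample variance of their (normalized, log2) expression
#' and retains the top `n`; ties are broken lexicographically by gene id
#' so the selection is deterministic.
#'
#' @param expr Genes x samples numeric matrix.
#' @param n Number of genes to keep (default 5000, the usual network
#'   input size).
#' @return Matrix restricted to the selected genes (original row order
#'   preserved), tagged with stage "filtered". If fewer than `n` genes are
#'   present, all are kept with a warning.
#' @export
filter_top_variable <- function(expr, n = 5000) {
  if (!is.numeric(n) || n < 1)
    stop("'n' must be a positive count", call. = FALSE)
  if (nrow(expr) <= n) {
    if (nrow(expr) < n)
      warning("matrix has fewer than ", n, " genes; keeping all")
    out <- expr
  } else {
    v <- apply(expr, 1, var)
    keep <- rownames(expr)[order(-v, rownames(expr))][seq_len(n)]
    out <- expr[rownames(expr) %in% keep, , drop = FALSE]
  }
  attr(out, "stage") <- "filtered"
  out
}
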