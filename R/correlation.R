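# Biweight midcorrelation and the gene-gene correlation matrix.

# Tukey-biweight transform of one vector. Returns the centered, weighted
# vector; falls back to mean-centering (Pearson) when the MAD is zero.
# attr "fallback" records whether the fallback fired.
.bicor_transform <- function(v) {
  med <- median(v)
  mav <- median(abs(v - med))          # unscaled MAD, as in bicor
  if (mav == 0) {
    out <- v - mean(v)
    attr(out, "fallback") <- TRUE
    return(out)
  }
  u <- (v - med) / (9 * mav)
  w <- (1 - u^2)^2 * (abs(u) < 1)
  out <- (v - med) * w
  attr(out, "fallback") <- FALSE
  out
}

.unit_norm <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) return(v)                # constant vector: correlation -> 0
  v / n
}

#' Biweight midcorrelation of two vectors
#'
#' Robust correlation using Tukey biweights around the median with the
#' standard 9*MAD tuning constant: observations further than 9 MADs from
#' the median get zero weight, and the correlation is computed between
#' the weighted median-centered vectors. If a vector has zero MAD the
#' computation falls back to Pearson centering for that vector, with a
#' warning.
#'
#' @param x,y Numeric vectors of equal length >= 4.
#' @return Correlation in [-1, 1].
#' @export
#' @examples
#' set.seed(1)
#' x <- rnorm(50); bicor(x, x)   # 1
bicor <- function(x, y) {
  if (length(x) != length(y) || length(x) < 4)
    stop("'x' and 'y' must have equal length >= 4", call. = FALSE)
  xt <- .bicor_transform(x)
  yt <- .bicor_transform(y)
  if (isTRUE(attr(xt, "fallback")) || isTRUE(attr(yt, "fallback")))
    warning("zero MAD; Pearson fallback used for that vector")
  r <- sum(.unit_norm(xt) * .unit_norm(yt))
  max(-1, min(1, r))
}

#' Pairwise gene-gene correlation matrix
#'
#' Computes all pairwise correlations between the rows (genes) of an
#' expression matrix, by biweight midcorrelation (default) or Pearson.
#' Genes with zero MAD use the Pearson fallback; constant genes get zero
#' correlation to everything and are flagged.
#'
#' @param expr Genes x samples numeric matrix with >= 4 samples.
#' @param method "bicor" or "pearson".
#' @return Symmetric genes x genes correlation matrix with unit diagonal;
#'   attributes `method` and `fallback_genes` (gene ids where the Pearson
#'   fallback or constant-gene rule fired).
#' @export
correlation_matrix <- function(expr, method = c("bicor", "pearson")) {
  method <- match.arg(method)
  if (ncol(expr) < 4)
    stop("at least 4 samples are required", call. = FALSE)
  n <- nrow(expr)
  if (method == "pearson") {
    cc <- cor(t(expr))
    fallback <- rownames(expr)[apply(expr, 1, sd) == 0]
    cc[is.na(cc)] <- 0
  } else {
    tr <- matrix(0, n, ncol(expr))
    fallback_flag <- logical(n)
    for (i in seq_len(n)) {
      v <- .bicor_transform(expr[i, ])
      fallback_flag[i] <- attr(v, "fallback")
      tr[i, ] <- .unit_norm(v)
    }
    cc <- tcrossprod(tr)
    cc[cc > 1] <- 1
    cc[cc < -1] <- -1
    fallback <- rownames(expr)[fallback_flag]
  }
  diag(cc) <- 1
  dimnames(cc) <- list(rownames(expr), rownames(expr))
  if (length(fallback))
    warning(length(fallback),
            " gene(s) used the Pearson/constant fallback")
  structure(cc, method = method, fallback_genes = fallback)
}
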