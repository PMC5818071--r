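# Module eigengenes, membership, gene/module-trait statistics, hubs.

# Standardize gene rows to zero mean, unit variance; constant rows -> 0.
.standardize_rows <- function(expr) {
  m <- rowMeans(expr)
  s <- apply(expr, 1, sd)
  s[s == 0] <- 1
  (expr - m) / s
}

#' Module eigengenes
#'
#' The eigengene of a module is the first principal component of its
#' standardized expression across samples: the leading left-singular
#' vector of the samples x genes submatrix, unit-norm over samples, with
#' the sign oriented so the mean correlation with the member genes is
#' positive.
#'
#' @param expr Genes x samples numeric matrix.
#' @param assignment Named gene -> module vector.
#' @param exclude Module labels to skip (default "grey").
#' @return List with `eigengenes` (modules x samples matrix) and
#'   `var_explained` (named vector; proportion of module variance carried
#'   by the eigengene).
#' @export
module_eigengene <- function(expr, assignment, exclude = "grey") {
  assignment <- assignment[rownames(expr)]
  modules <- setdiff(unique(assignment), exclude)
  if (length(modules) == 0)
    stop("no modules to summarize", call. = FALSE)
  scaled <- .standardize_rows(expr)
  me <- matrix(0, length(modules), ncol(expr),
               dimnames = list(modules, colnames(expr)))
  ve <- setNames(numeric(length(modules)), modules)
  for (m in modules) {
    sub <- t(scaled[assignment == m, , drop = FALSE])   # samples x genes
    sv <- svd(sub, nu = 1, nv = 0)
    e <- sv$u[, 1]
    if (mean(cor(e, sub)) < 0) e <- -e
    me[m, ] <- e
    ve[m] <- sv$d[1]^2 / sum(sv$d^2)
  }
  list(eigengenes = me, var_explained = ve)
}

#' Module membership (kME)
#'
#' Pearson correlation between each gene's expression profile and each
#' module eigengene.
#'
#' @param expr Genes x samples numeric matrix.
#' @param eigengenes Modules x samples eigengene matrix (the `eigengenes`
#'   component of [module_eigengene()]).
#' @return Genes x modules matrix of correlations.
#' @export
module_membership_kme <- function(expr, eigengenes) {
  kme <- cor(t(expr), t(eigengenes))
  kme[is.na(kme)] <- 0        # constant genes
  kme
}

#' Gene significance versus a sample trait
#'
#' GS is the Pearson correlation between each gene's expression and a
#' numeric (or 0/1-encoded binary) sample trait; p-values come from the
#' t distribution with n - 2 degrees of freedom.
#'
#' @param expr Genes x samples numeric matrix.
#' @param trait Numeric vector aligned to samples, or a two-level
#'   factor/character (encoded 0/1 by level order).
#' @return data.frame with gene, gs, p_value.
#' @export
gene_significance <- function(expr, trait) {
  if (is.character(trait) || is.factor(trait))
    trait <- as.numeric(factor(trait)) - 1
  if (length(trait) != ncol(expr))
    stop("trait must align with samples", call. = FALSE)
  if (var(trait) == 0)
    stop("trait is constant", call. = FALSE)
  gs <- as.vector(cor(t(expr), trait))
  gs[is.na(gs)] <- 0
  n <- ncol(expr)
  tt <- gs * sqrt((n - 2) / pmax(1 - gs^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tt), df = n - 2)
  data.frame(gene = rownames(expr), gs = gs, p_value = p,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Build standard trait indicators from a sample table
#'
#' One column per trait: a case-group indicator (1 = case) plus a
#' one-vs-rest indicator per time point.
#'
#' @param samples Sample table with `group` and `timepoint` columns.
#' @param case_group Case label (default "HS").
#' @return data.frame of 0/1 indicators, rows aligned to samples.
#' @export
trait_indicators <- function(samples, case_group = "HS") {
  out <- data.frame(row.names = samples$sample_id,
                    check.names = FALSE)
  out[[case_group]] <- as.integer(samples$group == case_group)
  for (tp in unique(samples$timepoint))
    out[[tp]] <- as.integer(samples$timepoint == tp)
  out
}

#' Module-trait relationship matrix
#'
#' Correlation (and p-value from the t distribution) between each module
#' eigengene and each trait column; modules are flagged significant for a
#' trait at p <= `p_threshold` (default 0.1, the module-level cutoff).
#'
#' @param eigengenes Modules x samples eigengene matrix.
#' @param traits data.frame/matrix of numeric traits, rows = samples in
#'   the eigengene column order.
#' @param p_threshold Module significance threshold (default 0.1).
#' @return List with matrices `correlation`, `p_value` and logical
#'   `significant`, all modules x traits.
#' @export
module_trait_matrix <- function(eigengenes, traits, p_threshold = 0.1) {
  traits <- as.matrix(traits)
  if (nrow(traits) != ncol(eigengenes))
    stop("traits must have one row per sample", call. = FALSE)
  cc <- cor(t(eigengenes), traits)
  n <- ncol(eigengenes)
  tt <- cc * sqrt((n - 2) / pmax(1 - cc^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tt), df = n - 2)
  list(correlation = cc, p_value = p, significant = p <= p_threshold)
}

#' Top hub genes per module by intramodular connectivity
#'
#' @param stats Gene network stats from [intramodular_connectivity()].
#' @param n Hubs per module (default 10). Modules with fewer members
#'   return all of them, flagged `short_module`.
#' @return data.frame with module, gene, kWithin, hub_rank, short_module;
#'   grey genes are excluded.
#' @export
top_hubs <- function(stats, n = 10) {
  if (!is.numeric(n) || n < 1)
    stop("'n' must be a positive count", call. = FALSE)
  stats <- stats[stats$module != "grey", , drop = FALSE]
  out <- lapply(split(stats, stats$module), function(ms) {
    ms <- ms[order(-ms$kWithin, ms$gene), , drop = FALSE]
    take <- head(ms, n)
    data.frame(module = take$module, gene = take$gene,
               kWithin = take$kWithin,
               hub_rank = seq_len(nrow(take)),
               short_module = nrow(ms) < n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Connectivity-significance scatter data for trait-associated genes
#'
#' Per module, the (kWithin, GS) pairs of genes whose gene-significance
#' p-value passes the cutoff, plus the per-module count of passing genes.
#'
#' @param stats Gene network stats from [intramodular_connectivity()].
#' @param gs data.frame from [gene_significance()].
#' @param gs_p_cutoff GS p-value cutoff (default 0.1).
#' @return List with `table` (module, gene, kWithin, gs, p_value) and
#'   `counts` (module, n_significant). Grey genes are excluded.
#' @export
gs_kwithin_scatter <- function(stats, gs, gs_p_cutoff = 0.1) {
  merged <- merge(stats[stats$module != "grey",
                        c("gene", "module", "kWithin")],
                  gs, by = "gene")
  pass <- merged[merged$p_value <= gs_p_cutoff, , drop = FALSE]
  pass <- pass[order(pass$module, -pass$kWithin), ]
  rownames(pass) <- NULL
  counts <- as.data.frame(table(factor(pass$module,
                                       levels = unique(merged$module))),
                          stringsAsFactors = FALSE)
  names(counts) <- c("module", "n_significant")
  list(table = pass[, c("module", "gene", "kWithin", "gs", "p_value")],
       counts = counts)
}
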