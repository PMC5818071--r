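# Unsigned weighted network: soft-threshold adjacency, scale-free fit,
# topological overlap, module detection, connectivity.

#' Soft-threshold adjacency matrix
#'
#' Unsigned weighted adjacency \eqn{a_{ij} = |cor_{ij}|^\beta}. The
#' diagonal is stored as zero so that row sums are node connectivities.
#'
#' @param cor_mat Symmetric correlation matrix (e.g. from
#'   [correlation_matrix()]).
#' @param beta Soft-threshold power, >= 1. The workflow default is 10.
#' @return Symmetric adjacency matrix in [0, 1] with zero diagonal and
#'   attribute `beta`.
#' @export
adjacency <- function(cor_mat, beta = 10) {
  if (!is.numeric(beta) || beta < 1)
    stop("'beta' must be >= 1", call. = FALSE)
  a <- abs(cor_mat)^beta
  diag(a) <- 0
  structure(a, beta = beta, method = NULL, fallback_genes = NULL)
}

#' Scale-free topology fit of a connectivity distribution
#'
#' Bins node connectivities into `n_bins` equal-width bins and regresses
#' log10 bin frequency on log10 mean bin connectivity over the non-empty
#' bins. The fit index is the R-squared of that regression when the slope
#' is negative (power-law decay) and 0 otherwise.
#'
#' @param k Numeric vector of node connectivities.
#' @param n_bins Number of equal-width bins (default 10).
#' @return List with `fit_index`, `r_squared` (raw), `slope`,
#'   `n_bins_used`.
#' @export
scale_free_fit <- function(k, n_bins = 10) {
  if (diff(range(k)) < .Machine$double.eps^0.5) {
    warning("all connectivities equal; fit index 0")
    return(list(fit_index = 0, r_squared = NA_real_, slope = NA_real_,
                n_bins_used = 0L))
  }
  bins <- cut(k, breaks = n_bins, include.lowest = TRUE, labels = FALSE)
  freq <- tabulate(bins, nbins = n_bins) / length(k)
  kmean <- tapply(k, factor(bins, levels = seq_len(n_bins)), mean)
  keep <- freq > 0 & !is.na(kmean) & kmean > 0
  if (sum(keep) < 3)
    stop("need at least 3 non-empty connectivity bins", call. = FALSE)
  fit <- lm(log10(freq[keep]) ~ log10(kmean[keep]))
  r2 <- summary(fit)$r.squared
  slope <- unname(coef(fit)[2])
  list(fit_index = if (slope < 0) r2 else 0,
       r_squared = r2, slope = slope, n_bins_used = sum(keep))
}

#' Select the soft-threshold power by scale-free topology fit
#'
#' For each candidate power, computes node connectivities under the
#' corresponding adjacency and the scale-free fit index; returns the
#' smallest power reaching `target_r2` (default 0.8), or, if none does,
#' the power maximizing the index, flagged.
#'
#' @param expr Genes x samples numeric matrix (>= 50 genes).
#' @param beta_grid Candidate powers (default 1:20).
#' @param target_r2 Fit-index target (default 0.8).
#' @param n_bins Connectivity bins for [scale_free_fit()].
#' @param method Correlation method, "bicor" (default) or "pearson".
#' @return List with `beta` (selected power), `reached_target` (logical),
#'   `fit_table` (data.frame beta, fit_index, slope, mean_k).
#' @export
pick_soft_threshold <- function(expr, beta_grid = 1:20, target_r2 = 0.8,
                                n_bins = 10,
                                method = c("bicor", "pearson")) {
  if (length(beta_grid) == 0)
    stop("'beta_grid' must be non-empty", call. = FALSE)
  if (nrow(expr) < 50)
    stop("soft-threshold selection needs at least 50 genes", call. = FALSE)
  abs_cor <- abs(suppressWarnings(correlation_matrix(expr, match.arg(method))))
  diag(abs_cor) <- 0
  rows <- lapply(beta_grid, function(beta) {
    k <- rowSums(abs_cor^beta)
    sf <- tryCatch(scale_free_fit(k, n_bins),
                   error = function(e) list(fit_index = 0,
                                            slope = NA_real_))
    data.frame(beta = beta, fit_index = sf$fit_index, slope = sf$slope,
               mean_k = mean(k))
  })
  fit_table <- do.call(rbind, rows)
  hit <- which(fit_table$fit_index >= target_r2)
  if (length(hit)) {
    beta <- fit_table$beta[hit[1]]
    reached <- TRUE
  } else {
    beta <- fit_table$beta[which.max(fit_table$fit_index)]
    reached <- FALSE
  }
  list(beta = beta, reached_target = reached, fit_table = fit_table)
}

#' Topological overlap similarity
#'
#' \deqn{TOM_{ij} = \frac{\sum_{u \ne i,j} a_{iu} a_{uj} + a_{ij}}
#'   {\min(k_i, k_j) + 1 - a_{ij}}, \qquad TOM_{ii} = 1.}
#' High overlap means two genes share neighbors in addition to any
#' direct connection; 1 - TOM is the module-detection dissimilarity.
#'
#' @param adj Adjacency matrix from [adjacency()] (zero diagonal).
#' @return Symmetric TOM matrix in [0, 1] with unit diagonal.
#' @export
tom_similarity <- function(adj) {
  k <- rowSums(adj)
  shared <- adj %*% adj                # includes no diagonal terms: diag 0
  num <- shared + adj
  kmin <- outer(k, k, pmin)
  tom <- num / (kmin + 1 - adj)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adj)
  tom
}

# Fixed color sequence for module labels, by decreasing module size;
# overflows past the palette become "module_<k>".
module_color_sequence <- function(n) {
  palette <- c("turquoise", "blue", "brown", "yellow", "green", "red",
               "black", "pink", "magenta", "purple", "greenyellow",
               "tan", "salmon", "cyan", "midnightblue", "lightcyan",
               "grey60", "lightgreen", "lightyellow", "royalblue",
               "darkred", "darkgreen", "darkturquoise", "darkgrey",
               "orange", "darkorange", "white", "skyblue", "saddlebrown",
               "steelblue", "paleturquoise", "violet", "darkolivegreen",
               "darkmagenta")
  if (n <= length(palette)) return(palette[seq_len(n)])
  c(palette, paste0("module_", seq_len(n - length(palette))))
}

#' Detect coexpression modules by hierarchical clustering of 1 - TOM
#'
#' Average-linkage hierarchical clustering on the dissimilarity 1 - TOM
#' (or 1 - |cor| if a raw-dissimilarity input is preferred), followed by
#' a static tree cut. The cut position is expressed as a fraction of the
#' merge-height span between its 5th percentile and its maximum
#' (anchoring at the 5th percentile rather than the minimum makes the
#' position insensitive to a single unusually tight gene pair). By
#' default the fraction is chosen automatically from a fixed grid: the
#' candidate producing the largest number of clusters of at least
#' `min_module_size` genes wins, and among those the lowest cut is used,
#' favoring tight, pure modules over looser ones that absorb peripheral
#' genes. This keeps a single static cut (reproducible, O(grid) extra
#' cost) while adapting to how tight the modules are. Clusters smaller than `min_module_size` are assigned
#' to "grey" (unassigned); surviving modules are labeled with color
#' names in decreasing size order (turquoise, blue, brown, ...).
#'
#' @param tom Similarity matrix in [0, 1] with unit diagonal (TOM or
#'   absolute correlation).
#' @param min_module_size Minimum genes per module (default 50).
#' @param cut_height "auto" (default) or a fixed fraction in (0, 1) of
#'   the merge-height span.
#' @return Named character vector gene id -> module label ("grey" for
#'   unassigned), with attributes `n_modules` and `cut_height` (the
#'   fraction used).
#' @export
detect_modules <- function(tom, min_module_size = 50,
                           cut_height = "auto") {
  if (min_module_size < 2)
    stop("'min_module_size' must be >= 2", call. = FALSE)
  genes <- rownames(tom)
  n <- length(genes)
  if (min_module_size > n) {
    warning("minimum module size exceeds gene count; all genes grey")
    return(structure(setNames(rep("grey", n), genes), n_modules = 0L))
  }
  tree <- hclust(as.dist(1 - tom), method = "average")
  lo <- quantile(tree$height, 0.05, names = FALSE)
  span <- max(tree$height) - lo
  if (identical(cut_height, "auto")) {
    grid <- c(seq(0.1, 0.9, by = 0.1), seq(0.92, 0.999, by = 0.004))
    best <- NULL
    for (f in grid) {
      cl <- cutree(tree, h = lo + f * span)
      sz <- table(cl)
      n_big <- sum(sz >= min_module_size)
      if (is.null(best) || n_big > best$n_big) {
        best <- list(n_big = n_big, f = f, raw = cl)
      }
    }
    cut_height <- best$f
    raw <- best$raw
  } else {
    if (!is.numeric(cut_height) || cut_height <= 0 || cut_height >= 1)
      stop("'cut_height' must be \"auto\" or a fraction in (0, 1)",
           call. = FALSE)
    raw <- cutree(tree, h = lo + cut_height * span)
  }
  sizes <- table(raw)
  keep <- names(sizes)[sizes >= min_module_size]
  labels <- setNames(rep("grey", n), genes)
  if (length(keep)) {
    # order surviving clusters by decreasing size; ties by first gene id
    keep_sizes <- sizes[keep]
    first_gene <- vapply(keep, function(cl)
      min(genes[raw == as.integer(cl)]), character(1))
    ord <- keep[order(-as.integer(keep_sizes), first_gene)]
    colors <- module_color_sequence(length(ord))
    for (i in seq_along(ord))
      labels[raw == as.integer(ord[i])] <- colors[i]
  }
  structure(labels, n_modules = length(keep), cut_height = cut_height)
}

#' Whole-network and intramodular connectivity
#'
#' For each gene, the total connectivity `kTotal` (sum of adjacency to
#' all other genes) and the intramodular connectivity `kWithin` (sum of
#' adjacency to co-members of its module). `kOut = kTotal - kWithin`
#' exactly. Grey genes get kWithin over grey co-members but are excluded
#' from hub and rank analyses downstream.
#'
#' @param adj Adjacency matrix (zero diagonal).
#' @param assignment Named module assignment covering all genes in `adj`.
#' @return data.frame with gene, module, kTotal, kWithin, kOut.
#' @export
intramodular_connectivity <- function(adj, assignment) {
  genes <- rownames(adj)
  if (!all(genes %in% names(assignment)))
    stop("assignment must cover every gene in the adjacency matrix",
         call. = FALSE)
  mod <- assignment[genes]
  k_total <- rowSums(adj)
  k_within <- numeric(length(genes))
  for (m in unique(mod)) {
    idx <- which(mod == m)
    k_within[idx] <- rowSums(adj[idx, idx, drop = FALSE])
  }
  data.frame(gene = genes, module = unname(mod),
             kTotal = unname(k_total), kWithin = k_within,
             kOut = unname(k_total) - k_within,
             row.names = NULL, stringsAsFactors = FALSE)
}
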