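# Paired reference-vs-test network comparison: connectivity rank change
# and permutation module-preservation Z statistics.

#' Build a reference/test network pair with shared module labels
#'
#' Builds one network per condition on the shared gene set at the same
#' soft-threshold power, detects modules in the reference (e.g. CTRL)
#' network and copies those labels onto the test (e.g. HS) network, so
#' module-level statistics are directly comparable.
#'
#' @param expr_ref,expr_test Genes x samples matrices for the reference
#'   and test condition. Genes outside the intersection are dropped with
#'   a warning; fewer than 50 shared genes is an error.
#' @param beta Soft-threshold power (default 10).
#' @param method Correlation method (default "bicor").
#' @param min_module_size,cut_height Module-detection parameters, see
#'   [detect_modules()].
#' @return Object of class `paired_networks`: list with `genes`,
#'   `adjacency_ref`, `adjacency_test`, `assignment`, `beta`,
#'   `stats_ref`, `stats_test` (per-gene connectivity under the shared
#'   assignment).
#' @export
build_paired_networks <- function(expr_ref, expr_test, beta = 10,
                                  method = c("bicor", "pearson"),
                                  min_module_size = 50,
                                  cut_height = "auto") {
  method <- match.arg(method)
  shared <- intersect(rownames(expr_ref), rownames(expr_test))
  dropped <- length(union(rownames(expr_ref), rownames(expr_test))) -
    length(shared)
  if (dropped > 0)
    warning(dropped, " gene(s) absent from one condition were dropped")
  if (length(shared) < 50)
    stop("fewer than 50 shared genes between conditions", call. = FALSE)
  expr_ref <- expr_ref[shared, , drop = FALSE]
  expr_test <- expr_test[shared, , drop = FALSE]

  adj_ref <- adjacency(suppressWarnings(
    correlation_matrix(expr_ref, method)), beta)
  adj_test <- adjacency(suppressWarnings(
    correlation_matrix(expr_test, method)), beta)
  assignment <- detect_modules(tom_similarity(adj_ref),
                               min_module_size = min_module_size,
                               cut_height = cut_height)
  structure(list(
    genes = shared,
    adjacency_ref = adj_ref,
    adjacency_test = adj_test,
    assignment = assignment,
    beta = beta,
    stats_ref = intramodular_connectivity(adj_ref, assignment),
    stats_test = intramodular_connectivity(adj_test, assignment)
  ), class = "paired_networks")
}

#' Rank genes by intramodular connectivity
#'
#' Dense ranks over all non-grey genes, 1 = largest kWithin; ties broken
#' by gene id so the ranking is deterministic.
#'
#' @param stats Gene network stats from [intramodular_connectivity()].
#' @return Named integer vector of ranks (grey genes excluded).
#' @export
rank_connectivity <- function(stats) {
  stats <- stats[stats$module != "grey", , drop = FALSE]
  ord <- order(-stats$kWithin, stats$gene)
  setNames(order(ord), stats$gene)[stats$gene]
}

#' Connectivity rank changes between a reference and a test network
#'
#' For every ranked gene, `delta_rank = rank_ref - rank_test` (positive =
#' the gene climbs in the test network, i.e. gains connectivity).
#' Modules are scored by the median member delta and by the count of
#' members with positive delta, and classified gain/loss/none by the
#' sign of the median.
#'
#' @param ranks_ref,ranks_test Named rank vectors from
#'   [rank_connectivity()] over the same gene set.
#' @param assignment Named gene -> module vector.
#' @return List with `gene_table` (gene, module, rank_ref, rank_test,
#'   delta_rank) and `module_table` (module, size, median_delta, n_gain,
#'   class), ordered by decreasing median delta.
#' @export
rank_change <- function(ranks_ref, ranks_test, assignment) {
  if (!setequal(names(ranks_ref), names(ranks_test)))
    stop("reference and test rankings cover different gene sets",
         call. = FALSE)
  genes <- names(ranks_ref)
  delta <- ranks_ref[genes] - ranks_test[genes]
  gene_table <- data.frame(
    gene = genes, module = unname(assignment[genes]),
    rank_ref = unname(ranks_ref[genes]),
    rank_test = unname(ranks_test[genes]),
    delta_rank = unname(delta),
    row.names = NULL, stringsAsFactors = FALSE)

  module_table <- do.call(rbind, lapply(
    split(gene_table, gene_table$module), function(ms) {
      med <- median(ms$delta_rank)
      data.frame(module = ms$module[1], size = nrow(ms),
                 median_delta = med,
                 n_gain = sum(ms$delta_rank > 0),
                 class = if (med > 0) "gain" else if (med < 0) "loss"
                         else "none",
                 stringsAsFactors = FALSE)
    }))
  module_table <- module_table[order(-module_table$median_delta,
                                     module_table$module), ]
  rownames(module_table) <- NULL
  list(gene_table = gene_table, module_table = module_table)
}

# Density and connectivity preservation statistics for one gene set.
.preservation_stats <- function(idx, adj_ref, adj_test) {
  sub_test <- adj_test[idx, idx, drop = FALSE]
  s <- length(idx)
  density <- sum(sub_test) / (s * (s - 1))
  k_ref <- rowSums(adj_ref[idx, idx, drop = FALSE])
  k_test <- rowSums(sub_test)
  conn <- suppressWarnings(cor(k_ref, k_test))
  if (is.na(conn)) conn <- 0
  c(density = density, connectivity = conn)
}

#' Permutation module-preservation Z statistics (Zsummary)
#'
#' For each non-grey module, the observed preservation statistics in the
#' test network are (i) density: mean off-diagonal test adjacency among
#' members, and (ii) connectivity: correlation between member
#' intramodular connectivity in the reference and in the test network.
#' A permutation null re-computes both statistics on random same-size
#' gene sets drawn from the non-grey genes; each Z is
#' (observed - null mean) / null SD and
#' `Zsummary = (Zdensity + Zconnectivity) / 2`. A "gold" module of
#' `gold_size` random genes is scored alongside as a baseline.
#' Classification: Zsummary < 2 none, > 10 strong, otherwise
#' weak-to-moderate.
#'
#' @param paired A [build_paired_networks()] object.
#' @param n_permutations Number of random gene sets (>= 50, default 100).
#' @param gold_size Size of the random gold module (default 1000, capped
#'   at the gene count).
#' @param seed Integer seed for all draws.
#' @return data.frame with module, size, density, connectivity,
#'   Zdensity, Zconnectivity, Zsummary, class; includes a "gold" row.
#'   Modules smaller than 3 genes are skipped with a warning; a zero
#'   null SD yields an infinite Z.
#' @export
preservation_zsummary <- function(paired, n_permutations = 100,
                                  gold_size = 1000, seed = 1L) {
  stopifnot(inherits(paired, "paired_networks"))
  if (n_permutations < 50)
    stop("'n_permutations' must be >= 50", call. = FALSE)
  genes <- paired$genes
  if (gold_size > length(genes)) {
    warning("gold size capped at the number of genes")
    gold_size <- length(genes)
  }
  set.seed(seed)
  assignment <- paired$assignment[genes]
  # null sets are random same-size gene sets from the whole test network,
  # so the null reflects what an arbitrary gene set of that size looks like
  pool <- seq_along(genes)

  modules <- setdiff(unique(assignment), "grey")
  small <- modules[vapply(modules,
                          function(m) sum(assignment == m) < 3, logical(1))]
  if (length(small)) {
    warning("module(s) smaller than 3 genes skipped: ",
            paste(small, collapse = ", "))
    modules <- setdiff(modules, small)
  }

  member_sets <- c(lapply(modules, function(m) which(assignment == m)),
                   list(sample(seq_along(genes), gold_size)))
  names(member_sets) <- c(modules, "gold")

  rows <- lapply(names(member_sets), function(m) {
    idx <- member_sets[[m]]
    obs <- .preservation_stats(idx, paired$adjacency_ref,
                               paired$adjacency_test)
    null <- vapply(seq_len(n_permutations), function(b) {
      .preservation_stats(sample(pool, length(idx)),
                          paired$adjacency_ref, paired$adjacency_test)
    }, numeric(2))
    mu <- rowMeans(null)
    sdev <- apply(null, 1, sd)
    z <- ifelse(sdev == 0,
                ifelse(obs > mu, Inf, ifelse(obs < mu, -Inf, 0)),
                (obs - mu) / sdev)
    data.frame(module = m, size = length(idx),
               density = obs[["density"]],
               connectivity = obs[["connectivity"]],
               Zdensity = z[["density"]],
               Zconnectivity = z[["connectivity"]],
               Zsummary = mean(z),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$class <- classify_preservation(out$Zsummary)
  rownames(out) <- NULL
  out
}

#' Classify a Zsummary preservation score
#'
#' Zsummary below 2 indicates no preservation, between 2 and 10 weak to
#' moderate evidence, above 10 strong module preservation.
#'
#' @param zsummary Numeric vector of Zsummary scores.
#' @return Character vector in {"none", "weak_moderate", "strong"}.
#' @export
classify_preservation <- function(zsummary) {
  ifelse(zsummary < 2, "none",
         ifelse(zsummary > 10, "strong", "weak_moderate"))
}
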