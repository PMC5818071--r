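# Orchestration of the full temporal analysis.

#' Analysis run configuration
#'
#' Collects every tunable of the workflow with the study defaults:
#' soft threshold 10 (with a scale-free fit check, or "auto" selection),
#' 5000 most-variable genes, minimum module size 50, SAM FDR target 10%,
#' 100 preservation permutations, 1000-gene gold module, GS p cutoff
#' 0.05, module p cutoff 0.1, 10 hubs per module.
#'
#' @param beta Soft-threshold power, or "auto" to select by scale-free
#'   fit per analysis.
#' @param top_n Number of most-variable genes entering the network.
#' @param min_module_size Minimum module size.
#' @param cut_height Tree-cut position: "auto" or a fraction of the
#'   merge-height span (see [detect_modules()]).
#' @param fdr_target SAM FDR target.
#' @param sam_permutations SAM label permutations.
#' @param n_permutations Preservation permutations.
#' @param gold_size Gold-module size.
#' @param gs_p_cutoff Gene-significance p cutoff.
#' @param module_p_cutoff Module-significance p cutoff.
#' @param hub_n Hubs reported per module.
#' @param method Correlation method for the network step.
#' @param seed Integer seed for all stochastic stages.
#' @return Object of class `run_config` (a validated list).
#' @export
run_config <- function(beta = 10, top_n = 5000, min_module_size = 50,
                       cut_height = "auto", fdr_target = 0.10,
                       sam_permutations = 200, n_permutations = 100,
                       gold_size = 1000, gs_p_cutoff = 0.05,
                       module_p_cutoff = 0.1, hub_n = 10,
                       method = "bicor", seed = 1L) {
  if (!identical(beta, "auto") && (!is.numeric(beta) || beta < 1))
    stop("'beta' must be \"auto\" or a power >= 1", call. = FALSE)
  for (p in c(fdr_target, gs_p_cutoff, module_p_cutoff))
    if (p <= 0 || p >= 1)
      stop("probability thresholds must be in (0, 1)", call. = FALSE)
  structure(list(beta = beta, top_n = top_n,
                 min_module_size = min_module_size,
                 cut_height = cut_height, fdr_target = fdr_target,
                 sam_permutations = sam_permutations,
                 n_permutations = n_permutations, gold_size = gold_size,
                 gs_p_cutoff = gs_p_cutoff,
                 module_p_cutoff = module_p_cutoff, hub_n = hub_n,
                 method = method, seed = as.integer(seed)),
            class = "run_config")
}

.validate_inputs <- function(expr, samples) {
  required <- c("sample_id", "group", "timepoint")
  missing <- setdiff(required, names(samples))
  if (length(missing))
    stop("sample table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (!setequal(colnames(expr), samples$sample_id))
    stop("expression columns and sample ids do not match", call. = FALSE)
  samples[match(colnames(expr), samples$sample_id), , drop = FALSE]
}

.resolve_beta <- function(expr, config) {
  if (identical(config$beta, "auto")) {
    sel <- pick_soft_threshold(expr, method = config$method)
    list(beta = sel$beta, fit_table = sel$fit_table,
         reached_target = sel$reached_target)
  } else {
    list(beta = config$beta, fit_table = NULL, reached_target = NA)
  }
}

#' Paired-network analysis of a single time point
#'
#' Runs the per-timepoint branch of the workflow on the samples of one
#' time point: variance filtering on the combined (both-group) matrix,
#' SAM differential expression (case vs control), paired network
#' construction with reference-derived module labels, connectivity
#' rank-change analysis, permutation module preservation, and hub
#' extraction.
#'
#' @param expr Genes x samples log2 expression matrix (all samples).
#' @param samples Sample table (`sample_id`, `group`, `timepoint`, ...).
#' @param config A [run_config()].
#' @param timepoint Time point label to analyze (default: all samples in
#'   `samples` are assumed to belong to one time point).
#' @param reference_group,case_group Group labels (defaults CTRL / HS).
#' @param out_dir Optional directory; when given, all result tables are
#'   written there as TSV.
#' @return List with `de` (sam_result), `paired` (paired_networks),
#'   `rank_change`, `preservation`, `hubs`, `beta`, `timepoint`.
#' @export
run_timepoint_analysis <- function(expr, samples, config = run_config(),
                                   timepoint = NULL,
                                   reference_group = "CTRL",
                                   case_group = "HS", out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  samples <- .validate_inputs(expr, samples)
  if (!is.null(timepoint)) {
    keep <- samples$timepoint == timepoint
    if (!any(keep)) stop("no samples at time point ", timepoint,
                         call. = FALSE)
    samples <- samples[keep, , drop = FALSE]
    expr <- expr[, samples$sample_id, drop = FALSE]
  } else {
    timepoint <- paste(unique(samples$timepoint), collapse = "+")
  }
  if (!all(c(reference_group, case_group) %in% samples$group))
    stop("both groups must be present at time point ", timepoint,
         call. = FALSE)

  filtered <- filter_top_variable(expr, config$top_n)

  de <- sam_permutation_fdr(filtered, samples$group,
                            B = config$sam_permutations,
                            target_fdr = config$fdr_target,
                            seed = config$seed)

  ref_cols <- samples$sample_id[samples$group == reference_group]
  case_cols <- samples$sample_id[samples$group == case_group]
  beta_sel <- .resolve_beta(filtered[, ref_cols, drop = FALSE], config)
  paired <- build_paired_networks(
    filtered[, ref_cols, drop = FALSE],
    filtered[, case_cols, drop = FALSE],
    beta = beta_sel$beta, method = config$method,
    min_module_size = config$min_module_size,
    cut_height = config$cut_height)

  rc <- rank_change(rank_connectivity(paired$stats_ref),
                    rank_connectivity(paired$stats_test),
                    paired$assignment)
  pres <- preservation_zsummary(paired,
                                n_permutations = config$n_permutations,
                                gold_size = config$gold_size,
                                seed = config$seed)
  hubs <- top_hubs(paired$stats_ref, config$hub_n)

  bundle <- list(timepoint = timepoint, beta = beta_sel$beta,
                 beta_fit = beta_sel$fit_table, de = de, paired = paired,
                 rank_change = rc, preservation = pres, hubs = hubs)
  if (!is.null(out_dir)) .write_timepoint_bundle(bundle, out_dir)
  bundle
}

.write_timepoint_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(bundle$de$stats, file.path(out_dir, "de_genes.tsv"))
  write_tsv(bundle$de$delta_table, file.path(out_dir, "de_delta.tsv"))
  write_tsv(bundle$rank_change$gene_table,
            file.path(out_dir, "rank_change_genes.tsv"))
  write_tsv(bundle$rank_change$module_table,
            file.path(out_dir, "rank_change_modules.tsv"))
  write_tsv(bundle$preservation, file.path(out_dir, "preservation.tsv"))
  write_tsv(bundle$hubs, file.path(out_dir, "hubs.tsv"))
  stats <- bundle$paired$stats_ref
  write_tsv(stats, file.path(out_dir, "gene_stats_reference.tsv"))
  invisible(out_dir)
}

#' Joint all-sample network and module-trait analysis
#'
#' Builds a single network over every sample, detects modules, and
#' relates module eigengenes to the case-group indicator and per-time-
#' point indicators; reports gene significance versus the case group and
#' the connectivity/GS scatter data for trait-associated genes.
#'
#' @inheritParams run_timepoint_analysis
#' @return List with `assignment`, `beta`, `eigengenes`,
#'   `module_trait` (correlation/p/significant matrices), `gs`
#'   (gene significance vs case), `significant_genes` (GS p <=
#'   `gs_p_cutoff`), `scatter`, `stats`.
#' @export
run_joint_analysis <- function(expr, samples, config = run_config(),
                               case_group = "HS", out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  samples <- .validate_inputs(expr, samples)
  filtered <- filter_top_variable(expr, config$top_n)

  beta_sel <- .resolve_beta(filtered, config)
  adj <- adjacency(suppressWarnings(
    correlation_matrix(filtered, config$method)), beta_sel$beta)
  assignment <- detect_modules(tom_similarity(adj),
                               min_module_size = config$min_module_size,
                               cut_height = config$cut_height)
  stats <- intramodular_connectivity(adj, assignment)

  me <- module_eigengene(filtered, assignment)
  traits <- trait_indicators(samples, case_group)
  mt <- module_trait_matrix(me$eigengenes, traits,
                            p_threshold = config$module_p_cutoff)
  gs <- gene_significance(filtered,
                          as.integer(samples$group == case_group))
  scatter <- gs_kwithin_scatter(stats, gs, gs_p_cutoff = 0.1)
  significant_genes <- gs[gs$p_value <= config$gs_p_cutoff, , drop = FALSE]

  bundle <- list(beta = beta_sel$beta, beta_fit = beta_sel$fit_table,
                 assignment = assignment, stats = stats,
                 eigengenes = me, module_trait = mt, gs = gs,
                 significant_genes = significant_genes,
                 scatter = scatter)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(stats, file.path(out_dir, "gene_stats.tsv"))
    me_df <- data.frame(module = rownames(me$eigengenes),
                        me$eigengenes, check.names = FALSE)
    write_tsv(me_df, file.path(out_dir, "eigengenes.tsv"))
    mt_df <- data.frame(module = rownames(mt$correlation),
                        mt$correlation, check.names = FALSE)
    write_tsv(mt_df, file.path(out_dir, "module_trait_correlation.tsv"))
    write_tsv(gs, file.path(out_dir, "gene_significance.tsv"))
    write_tsv(scatter$table, file.path(out_dir, "gs_kwithin_scatter.tsv"))
  }
  bundle
}
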