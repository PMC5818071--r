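#' Relative qPCR quantification by the delta-delta-Ct method
#'
#' For each target gene, \eqn{\Delta Ct_s = Ct_{target,s} - Ct_{ref,s}}
#' (normalization to a housekeeping gene, e.g. Gapdh),
#' \eqn{\Delta\Delta Ct_s = \Delta Ct_s - \overline{\Delta Ct}_{ctrl}},
#' and relative expression \eqn{2^{-\Delta\Delta Ct}}. Groups are
#' compared by a two-sample t test on \eqn{\Delta Ct}.
#'
#' @param ct Long-format data.frame with columns `sample_id`, `group`,
#'   `gene`, `ct` (cycle-threshold values, one row per sample x gene).
#' @param reference_gene Housekeeping gene used for normalization
#'   (default "Gapdh"); a reference Ct must exist for every sample.
#' @param control_group Label of the calibrator group (default "CTRL").
#' @param p_threshold Significance threshold for the t test (default 0.1).
#' @return List with `per_sample` (sample_id, group, gene, dct, ddct,
#'   rel_expr) and `per_gene` (gene, fold_change = 2^-mean case ddct,
#'   p_value, significant).
#' @export
delta_delta_ct <- function(ct, reference_gene = "Gapdh",
                           control_group = "CTRL", p_threshold = 0.1) {
  required <- c("sample_id", "group", "gene", "ct")
  if (!all(required %in% names(ct)))
    stop("ct table needs columns: ", paste(required, collapse = ", "),
         call. = FALSE)
  if (any(ct$ct <= 0))
    stop("Ct values must be positive", call. = FALSE)
  ref <- ct[ct$gene == reference_gene, ]
  targets <- ct[ct$gene != reference_gene, ]
  if (nrow(targets) == 0)
    stop("no target genes in the Ct table", call. = FALSE)
  missing_ref <- setdiff(unique(targets$sample_id), ref$sample_id)
  if (length(missing_ref))
    stop("missing reference Ct for sample(s): ",
         paste(missing_ref, collapse = ", "), call. = FALSE)
  if (!control_group %in% ct$group)
    stop("control group '", control_group, "' absent", call. = FALSE)
  if (length(unique(ct$group)) != 2)
    stop("exactly two groups are required", call. = FALSE)

  ref_ct <- setNames(ref$ct, ref$sample_id)
  targets$dct <- targets$ct - ref_ct[targets$sample_id]

  per_sample <- do.call(rbind, lapply(split(targets, targets$gene),
                                      function(tg) {
    ctrl_mean <- mean(tg$dct[tg$group == control_group])
    tg$ddct <- tg$dct - ctrl_mean
    tg$rel_expr <- 2^(-tg$ddct)
    tg
  }))
  rownames(per_sample) <- NULL

  per_gene <- do.call(rbind, lapply(split(per_sample, per_sample$gene),
                                    function(tg) {
    case <- tg$group != control_group
    # equal-variance two-sample t test; replicate-free or zero-variance
    # data cannot be tested, so the p-value degenerates to 1 (equal
    # means) or 0 (different means)
    pooled_var <- (sum((tg$dct[case] - mean(tg$dct[case]))^2) +
                     sum((tg$dct[!case] - mean(tg$dct[!case]))^2))
    p <- if (pooled_var < .Machine$double.eps) {
      if (abs(mean(tg$dct[case]) - mean(tg$dct[!case])) <
          .Machine$double.eps^0.5) 1 else 0
    } else {
      t.test(tg$dct[case], tg$dct[!case], var.equal = TRUE)$p.value
    }
    data.frame(gene = tg$gene[1],
               fold_change = 2^(-mean(tg$ddct[case])),
               p_value = p,
               significant = p < p_threshold,
               stringsAsFactors = FALSE)
  }))
  rownames(per_gene) <- NULL

  list(per_sample = per_sample[, c("sample_id", "group", "gene",
                                   "dct", "ddct", "rel_expr")],
       per_gene = per_gene)
}
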