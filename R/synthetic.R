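#' Configuration for the synthetic expression-data generator
#'
#' Describes a two-group (CTRL vs HS), multi-timepoint expression dataset
#' with block-correlated modules driven by latent sample-level factors,
#' uncorrelated background genes, optional condition-specific connectivity
#' perturbations and planted mean-shift differential genes.
#'
#' Each module gene i in module m has expression
#' \deqn{x_{is} = b + l_i u_{ms} + \epsilon_{is},}
#' where \eqn{u_{ms}} is a standard-normal latent factor drawn per module
#' and sample, \eqn{l_i} is a per-gene loading drawn uniformly from
#' `loading_range`, \eqn{\epsilon} is Gaussian noise with SD `noise_sd`,
#' and \eqn{b} is `baseline` (so values resemble log2 intensities).
#'
#' Perturbations act on the HS samples only, leaving CTRL as the shared
#' reference condition:
#' * `"gain"` — loadings multiplied by `gain_factor` (tighter coexpression),
#' * `"loss"` — loadings divided by `gain_factor`,
#' * `"destroy"` — module genes become pure baseline + noise,
#' * `"none"` — identical generative law in both groups.
#'
#' Differential genes are drawn from the background pool (so DE truth and
#' module-perturbation truth never overlap) and receive a +/- `de_effect`
#' shift of the HS mean.
#'
#' @param module_sizes Integer vector of planted module sizes (each >= 2).
#' @param n_background Number of independent background genes.
#' @param n_samples_per_group Samples per group per time point.
#' @param groups Group labels; the second is the perturbed (case) group.
#' @param timepoints Time point labels.
#' @param loading_range Length-2 numeric in (0, 1]; per-gene loadings are
#'   Uniform(loading_range).
#' @param noise_sd Gaussian noise standard deviation (> 0).
#' @param perturbations Named character vector mapping module labels
#'   ("M1", "M2", ...) to one of "none", "gain", "loss", "destroy".
#'   Unnamed modules default to "none".
#' @param gain_factor Loading multiplier (> 1) for "gain"/"loss" modules.
#' @param de_genes Number of planted differential genes (<= n_background).
#' @param de_effect Mean shift, in log2 units, added to HS samples of
#'   planted DE genes (sign per gene is random).
#' @param baseline Global additive baseline on the log2 scale.
#' @param seed Integer seed; all randomness in [generate_dataset()] flows
#'   from it.
#'
#' @return An object of class `synthetic_config` (a validated list).
#' @seealso [generate_dataset()]
#' @export
#' @examples
#' cfg <- synthetic_config(module_sizes = c(60, 40), n_background = 100,
#'                         n_samples_per_group = 4, timepoints = "P12")
synthetic_config <- function(module_sizes = c(300, 250, 200, 150, 100, 80),
                             n_background = 1000,
                             n_samples_per_group = 8,
                             groups = c("CTRL", "HS"),
                             timepoints = c("P12", "P30", "P60", "P120"),
                             loading_range = c(0.4, 0.9),
                             noise_sd = 1.0,
                             perturbations = character(0),
                             gain_factor = 2.0,
                             de_genes = 0,
                             de_effect = 1.0,
                             baseline = 8,
                             seed = 1L) {
  module_sizes <- as.integer(module_sizes)
  if (length(module_sizes) < 1 || any(module_sizes < 2))
    stop("each module size must be >= 2", call. = FALSE)
  if (n_background < 0)
    stop("'n_background' must be non-negative", call. = FALSE)
  if (!is.numeric(noise_sd) || noise_sd <= 0)
    stop("'noise_sd' must be a positive number", call. = FALSE)
  if (gain_factor <= 1)
    stop("'gain_factor' must be > 1", call. = FALSE)
  if (length(loading_range) != 2 || any(loading_range <= 0) ||
      loading_range[1] > loading_range[2])
    stop("'loading_range' must be an increasing pair of positive numbers",
         call. = FALSE)
  if (length(groups) != 2)
    stop("exactly two groups are required", call. = FALSE)
  if (de_genes > n_background)
    stop("'de_genes' cannot exceed 'n_background'", call. = FALSE)

  module_labels <- paste0("M", seq_along(module_sizes))
  pert <- setNames(rep("none", length(module_labels)), module_labels)
  if (length(perturbations)) {
    bad <- setdiff(names(perturbations), module_labels)
    if (length(bad))
      stop("unknown module label(s) in 'perturbations': ",
           paste(bad, collapse = ", "), call. = FALSE)
    if (!all(perturbations %in% c("none", "gain", "loss", "destroy")))
      stop("perturbations must be one of none/gain/loss/destroy",
           call. = FALSE)
    pert[names(perturbations)] <- perturbations
  }

  structure(list(
    n_genes = sum(module_sizes) + as.integer(n_background),
    module_sizes = module_sizes,
    module_labels = module_labels,
    n_background = as.integer(n_background),
    n_samples_per_group = as.integer(n_samples_per_group),
    groups = groups,
    timepoints = timepoints,
    loading_range = loading_range,
    noise_sd = noise_sd,
    perturbations = pert,
    gain_factor = gain_factor,
    de_genes = as.integer(de_genes),
    de_effect = de_effect,
    baseline = baseline,
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

#' Generate a synthetic expression dataset with known truth
#'
#' Simulates a log2-scale expression matrix under the latent-factor block
#' model described in [synthetic_config()], together with its sample
#' metadata and the planted ground truth (module membership, perturbation
#' per module, DE genes with direction).
#'
#' @param config A [synthetic_config()] object.
#' @return A list with components:
#' \describe{
#'   \item{expr}{numeric matrix, genes x samples, log2 scale.}
#'   \item{samples}{data.frame with sample_id, group, timepoint, sex.}
#'   \item{truth}{list with `module_of_gene` (named character; planted
#'     module label or "background"), `perturbation_of_module`,
#'     `de_gene_ids`, `de_direction` (named "up"/"down") and
#'     `latent_factors` (modules x samples matrix of the generating
#'     factors, for recovery checks).}
#' }
#' The same config (including seed) yields an identical dataset.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)

  case <- config$groups[2]
  samples <- expand.grid(
    replicate = seq_len(config$n_samples_per_group),
    timepoint = config$timepoints,
    group = config$groups,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  samples <- samples[, c("group", "timepoint", "replicate")]
  samples$sample_id <- sprintf("%s_%s_%02d", samples$group,
                               samples$timepoint, samples$replicate)
  samples$sex <- rep_len(c("F", "M"), nrow(samples))
  samples <- samples[, c("sample_id", "group", "timepoint", "sex")]
  n_samp <- nrow(samples)
  is_case <- samples$group == case

  n_mod_genes <- sum(config$module_sizes)
  gene_ids <- sprintf("g%04d", seq_len(config$n_genes))
  module_of_gene <- setNames(
    c(rep(config$module_labels, config$module_sizes),
      rep("background", config$n_background)),
    gene_ids)

  expr <- matrix(rnorm(config$n_genes * n_samp, mean = 0,
                       sd = config$noise_sd),
                 nrow = config$n_genes, ncol = n_samp,
                 dimnames = list(gene_ids, samples$sample_id))
  expr <- expr + config$baseline

  latent <- matrix(0, length(config$module_labels), n_samp,
                   dimnames = list(config$module_labels,
                                   samples$sample_id))
  row_offset <- 0L
  for (m in seq_along(config$module_labels)) {
    sz <- config$module_sizes[m]
    rows <- row_offset + seq_len(sz)
    row_offset <- row_offset + sz
    u <- rnorm(n_samp)                           # latent factor per sample
    latent[m, ] <- u
    loadings <- runif(sz, config$loading_range[1], config$loading_range[2])
    pert <- config$perturbations[config$module_labels[m]]
    load_mat <- outer(loadings, rep(1, n_samp))
    if (pert == "gain")  load_mat[, is_case] <- load_mat[, is_case] * config$gain_factor
    if (pert == "loss")  load_mat[, is_case] <- load_mat[, is_case] / config$gain_factor
    if (pert == "destroy") load_mat[, is_case] <- 0
    expr[rows, ] <- expr[rows, ] + load_mat * rep(u, each = sz)
  }

  de_gene_ids <- character(0)
  de_direction <- character(0)
  if (config$de_genes > 0) {
    background_ids <- gene_ids[module_of_gene == "background"]
    de_gene_ids <- sort(sample(background_ids, config$de_genes))
    signs <- sample(c(1, -1), config$de_genes, replace = TRUE)
    de_direction <- setNames(ifelse(signs > 0, "up", "down"), de_gene_ids)
    expr[de_gene_ids, is_case] <- expr[de_gene_ids, is_case] +
      signs * config$de_effect
  }

  list(
    expr = expr,
    samples = samples,
    truth = list(
      module_of_gene = module_of_gene,
      perturbation_of_module = config$perturbations,
      de_gene_ids = de_gene_ids,
      de_direction = de_direction,
      latent_factors = latent
    )
  )
}

#' Write a synthetic dataset to tab-delimited fixture files
#'
#' Writes the expression matrix, sample table and planted truth as TSV
#' files that round-trip losslessly through [read_expression()],
#' [read_samples()] and [read_truth()].
#'
#' @param dataset List as returned by [generate_dataset()] (components
#'   `expr` and `samples`).
#' @param truth Planted-truth list (`dataset$truth`).
#' @param directory Output directory (created if absent).
#' @return Invisibly, a named character vector of the three file paths
#'   (`expression`, `samples`, `truth`).
#' @export
write_fixture <- function(dataset, truth, directory) {
  if (is.null(dim(dataset$expr)) || nrow(dataset$expr) == 0)
    stop("refusing to write an empty expression matrix", call. = FALSE)
  if (!dir.exists(directory) &&
      !dir.create(directory, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create directory: ", directory, call. = FALSE)

  paths <- c(expression = file.path(directory, "expression.tsv"),
             samples = file.path(directory, "samples.tsv"),
             truth = file.path(directory, "truth.tsv"))

  write_expression(dataset$expr, paths[["expression"]])
  write_tsv(dataset$samples, paths[["samples"]])

  truth_df <- data.frame(
    gene_id = names(truth$module_of_gene),
    module = unname(truth$module_of_gene),
    perturbation = unname(ifelse(
      truth$module_of_gene %in% names(truth$perturbation_of_module),
      truth$perturbation_of_module[truth$module_of_gene], "none")),
    de = names(truth$module_of_gene) %in% truth$de_gene_ids,
    de_direction = ifelse(
      names(truth$module_of_gene) %in% truth$de_gene_ids,
      truth$de_direction[names(truth$module_of_gene)], ""),
    stringsAsFactors = FALSE
  )
  write_tsv(truth_df, paths[["truth"]])
  invisible(paths)
}
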