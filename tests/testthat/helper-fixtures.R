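# Shared fixture builders; everything is generated in code at test time.

# Small random expression matrix with gene/sample names.
random_expr <- function(n_genes, n_samples, seed = 1) {
  set.seed(seed)
  matrix(rnorm(n_genes * n_samples),
         nrow = n_genes, ncol = n_samples,
         dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                         sprintf("s%02d", seq_len(n_samples))))
}

# Block-structured expression: `blocks` tight modules of `block_size`
# highly correlated genes plus `n_noise` independent genes. noise_sd
# near 0 gives essentially noiseless blocks.
block_expr <- function(blocks = 3, block_size = 60, n_noise = 50,
                       n_samples = 20, noise_sd = 0.05, seed = 1) {
  set.seed(seed)
  rows <- list()
  truth <- character(0)
  for (b in seq_len(blocks)) {
    u <- rnorm(n_samples)
    block <- t(sapply(seq_len(block_size), function(i)
      u + rnorm(n_samples, sd = noise_sd)))
    rows[[b]] <- block
    truth <- c(truth, rep(paste0("B", b), block_size))
  }
  noise <- matrix(rnorm(n_noise * n_samples), n_noise, n_samples)
  x <- rbind(do.call(rbind, rows), noise)
  truth <- c(truth, rep("noise", n_noise))
  rownames(x) <- sprintf("g%03d", seq_len(nrow(x)))
  colnames(x) <- sprintf("s%02d", seq_len(n_samples))
  names(truth) <- rownames(x)
  list(expr = x, truth = truth)
}

# Small paired CTRL/HS synthetic dataset for comparison tests.
small_paired <- function(seed = 7, perturbations = c(M2 = "destroy")) {
  cfg <- synthetic_config(module_sizes = c(120, 120), n_background = 160,
                          n_samples_per_group = 8,
                          timepoints = c("P12", "P30"),
                          loading_range = c(0.5, 0.9), noise_sd = 1,
                          perturbations = perturbations, seed = seed)
  ds <- generate_dataset(cfg)
  ctrl <- ds$samples$sample_id[ds$samples$group == "CTRL"]
  hs <- ds$samples$sample_id[ds$samples$group == "HS"]
  list(ds = ds,
       expr_ctrl = ds$expr[, ctrl],
       expr_hs = ds$expr[, hs])
}

# Map each detected module label to the planted module holding the
# plurality of its genes.
map_detected_to_planted <- function(assignment, truth) {
  mods <- setdiff(unique(assignment), "grey")
  vapply(mods, function(m) {
    ov <- table(truth[names(assignment)[assignment == m]])
    names(which.max(ov))
  }, character(1))
}
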