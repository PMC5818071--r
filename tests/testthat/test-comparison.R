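test_that("identical conditions give identical paired networks", {
  sp <- block_expr(blocks = 2, block_size = 60, n_noise = 30,
                   n_samples = 16, noise_sd = 0.3, seed = 1)
  paired <- build_paired_networks(sp$expr, sp$expr, beta = 6)
  expect_identical(paired$adjacency_ref, paired$adjacency_test)
  expect_identical(paired$stats_ref, paired$stats_test)
  expect_true(all(names(paired$assignment) == paired$genes))
})

test_that("genes missing from one condition are dropped with a warning", {
  sp <- block_expr(blocks = 1, block_size = 60, n_noise = 30,
                   n_samples = 16, noise_sd = 0.3, seed = 2)
  expect_warning(
    paired <- build_paired_networks(sp$expr, sp$expr[-(1:5), ], beta = 6),
    "dropped")
  expect_length(paired$genes, nrow(sp$expr) - 5)
  suppressWarnings(
    expect_error(build_paired_networks(sp$expr[1:30, ], sp$expr[31:60, ],
                                       beta = 6), "50 shared"))
})

test_that("connectivity ranking is dense, deterministic and oracle-true", {
  stats <- data.frame(gene = c("a", "b", "c", "d"),
                      module = "blue",
                      kWithin = c(5, 4, 3, 2))
  expect_equal(unname(rank_connectivity(stats)), 1:4)

  stats$kWithin <- c(4, 4, 9, 1)   # tie between a and b
  r <- rank_connectivity(stats)
  expect_equal(r[["c"]], 1)
  expect_equal(r[["a"]], 2)        # id order breaks the tie
  expect_equal(r[["b"]], 3)

  set.seed(3)
  big <- data.frame(gene = sprintf("g%03d", 1:100), module = "m",
                    kWithin = runif(100))
  r_big <- rank_connectivity(big)
  oracle <- rank(-big$kWithin, ties.method = "first")
  expect_equal(unname(r_big[big$gene]), oracle)
})

test_that("rank changes follow the arithmetic and sum to zero", {
  ranks_ref <- c(a = 1, b = 2, c = 3, d = 4)
  ranks_test <- c(a = 4, b = 1, c = 2, d = 3)
  assignment <- c(a = "blue", b = "blue", c = "brown", d = "brown")
  rc <- rank_change(ranks_ref, ranks_test, assignment)
  expect_equal(rc$gene_table$delta_rank, c(-3, 1, 1, 1))
  expect_equal(sum(rc$gene_table$delta_rank), 0)

  same <- rank_change(ranks_ref, ranks_ref, assignment)
  expect_true(all(same$gene_table$delta_rank == 0))
  expect_true(all(same$module_table$class == "none"))

  expect_error(rank_change(ranks_ref, ranks_test[1:3], assignment),
               "different gene sets")
})

test_that("a planted connectivity-gain module tops the rank-change table", {
  hits <- 0
  for (s in 1:5) {
    sp <- small_paired(seed = 100 + s, perturbations = c(M2 = "gain"))
    paired <- suppressWarnings(build_paired_networks(
      sp$expr_ctrl, sp$expr_hs, beta = 10))
    map <- map_detected_to_planted(paired$assignment,
                                   sp$ds$truth$module_of_gene)
    if (!"M2" %in% map) next
    rc <- rank_change(rank_connectivity(paired$stats_ref),
                      rank_connectivity(paired$stats_test),
                      paired$assignment)
    top <- rc$module_table$module[1]
    if (identical(unname(map[top]), "M2")) hits <- hits + 1
  }
  expect_gte(hits, 4)
})

test_that("stronger gain factors produce larger median rank gains", {
  med_delta <- sapply(c(1.5, 2.5, 4), function(gf) {
    deltas <- sapply(1:3, function(s) {
      cfg <- synthetic_config(module_sizes = c(120, 120),
                              n_background = 160,
                              n_samples_per_group = 8,
                              timepoints = c("P12", "P30"),
                              loading_range = c(0.5, 0.9),
                              perturbations = c(M2 = "gain"),
                              gain_factor = gf, seed = 300 + s)
      ds <- generate_dataset(cfg)
      ctrl <- ds$samples$sample_id[ds$samples$group == "CTRL"]
      hs <- ds$samples$sample_id[ds$samples$group == "HS"]
      paired <- suppressWarnings(
        build_paired_networks(ds$expr[, ctrl], ds$expr[, hs], beta = 10))
      map <- map_detected_to_planted(paired$assignment,
                                     ds$truth$module_of_gene)
      lab <- names(map)[map == "M2"][1]
      if (is.na(lab)) return(NA_real_)
      rc <- rank_change(rank_connectivity(paired$stats_ref),
                        rank_connectivity(paired$stats_test),
                        paired$assignment)
      rc$module_table$median_delta[rc$module_table$module == lab]
    })
    mean(deltas, na.rm = TRUE)
  })
  expect_true(all(diff(med_delta) > 0))
})

test_that("preservation separates intact from destroyed modules", {
  sp <- small_paired(seed = 7, perturbations = c(M2 = "destroy"))
  paired <- build_paired_networks(sp$expr_ctrl, sp$expr_hs, beta = 10)
  map <- map_detected_to_planted(paired$assignment,
                                 sp$ds$truth$module_of_gene)
  pres <- suppressWarnings(
    preservation_zsummary(paired, n_permutations = 60, gold_size = 100,
                          seed = 7))
  z <- setNames(pres$Zsummary, pres$module)
  lab_preserved <- names(map)[map == "M1"][1]
  lab_destroyed <- names(map)[map == "M2"][1]
  # at this reduced size (120-gene modules, 16 samples per group) the
  # preserved module must still show at least weak evidence, clearly
  # separated from the destroyed one; the full-size separation (>10 vs
  # <2) is asserted in the acceptance suite
  expect_gt(z[[lab_preserved]], 2)
  expect_lt(z[[lab_destroyed]], 2)
  expect_gt(z[[lab_preserved]], z[[lab_destroyed]] + 3)
  expect_equal(pres$class[pres$module == lab_destroyed], "none")
  # gold baseline sits near zero
  expect_lt(abs(z[["gold"]]), 2)
})

test_that("preservation is reproducible and respects the gold size", {
  sp <- small_paired(seed = 9, perturbations = character(0))
  paired <- build_paired_networks(sp$expr_ctrl, sp$expr_hs, beta = 10)
  a <- suppressWarnings(preservation_zsummary(paired, 50, 100, seed = 4))
  b <- suppressWarnings(preservation_zsummary(paired, 50, 100, seed = 4))
  expect_identical(a, b)
  expect_equal(a$size[a$module == "gold"], 100)
  expect_warning(preservation_zsummary(paired, 50, 10000, seed = 4),
                 "capped")
})

test_that("self-comparison maximizes the connectivity statistic", {
  sp <- block_expr(blocks = 2, block_size = 60, n_noise = 40,
                   n_samples = 16, noise_sd = 0.4, seed = 5)
  paired <- build_paired_networks(sp$expr, sp$expr, beta = 6)
  pres <- suppressWarnings(
    preservation_zsummary(paired, 50, 50, seed = 1))
  mods <- pres$module != "gold"
  expect_true(all(pres$connectivity[mods] == 1))
  expect_true(all(pres$Zsummary[mods] > 2))
})

test_that("Zsummary classification uses the 2 and 10 thresholds", {
  expect_equal(classify_preservation(c(1.9, 2, 5, 10, 10.5, -3)),
               c("none", "weak_moderate", "weak_moderate",
                 "weak_moderate", "strong", "none"))
})
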