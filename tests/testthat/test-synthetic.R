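test_that("toy genome generation is seed-deterministic and validates sizing", {
  g1 <- generate_toy_genome(1, 1e6, 10, 20, seed = 1)
  g2 <- generate_toy_genome(1, 1e6, 10, 20, seed = 1)
  expect_identical(g1, g2)
  g3 <- generate_toy_genome(1, 1e6, 10, 20, seed = 2)
  expect_false(identical(g1$genes, g3$genes))
  expect_error(generate_toy_genome(1, 1000, 500, 0, seed = 1), "too small")
})

test_that("toy genome invariants hold under a property sweep", {
  for (seed in 1:5) {
    g <- generate_toy_genome(2, 1e6, 50, 100, seed = seed)
    chrlen <- setNames(g$chromosomes$length, g$chromosomes$name)
    # all intervals within bounds
    for (df in list(g$genes, g$exons, g$cgis)) {
      expect_true(all(df$start >= 0))
      expect_true(all(df$end <= chrlen[df$chrom]))
      expect_true(all(df$end > df$start))
    }
    # every gene has >= 1 exon, exons ordered and non-overlapping within gene
    expect_setequal(unique(g$exons$gene_id), g$genes$gene_id)
    for (gid in g$genes$gene_id) {
      ex <- g$exons[g$exons$gene_id == gid, ]
      ex <- ex[order(ex$start), ]
      gene <- g$genes[g$genes$gene_id == gid, ]
      expect_gte(nrow(ex), 1)
      expect_true(all(ex$start >= gene$start) && all(ex$end <= gene$end))
      if (nrow(ex) > 1) expect_true(all(ex$start[-1] >= ex$end[-nrow(ex)]))
    }
    # genes non-overlapping per chromosome
    for (cn in g$chromosomes$name) {
      gg <- g$genes[g$genes$chrom == cn, ]
      gg <- gg[order(gg$start), ]
      if (nrow(gg) > 1) expect_true(all(gg$start[-1] >= gg$end[-nrow(gg)]))
    }
    expect_identical(g$spared_chrom, "chr2")
  }
})

test_that("null landscape yields uniform tag rates; effects multiply density", {
  g <- generate_toy_genome(1, 1e6, 5, 5, seed = 3)
  cfg <- simulation_config(seed = 9, n_samples = c(CTRL = 1, PILO = 1),
                           depth = 1e5, duplicate_rate = 0)
  null_ls <- methylation_landscape(g)
  tags <- simulate_capture_tags(g, null_ls, cfg)
  t1 <- tags[tags$sample == "CTRL_1", ]
  # uniformity: chi-square over 20 bins should not be extreme
  bins <- table(cut(t1$pos5, seq(0, 1e6, length.out = 21)))
  chi <- sum((bins - mean(bins))^2 / mean(bins))
  expect_lt(chi, qchisq(1 - 1e-4, df = 19))

  eff <- data.frame(chrom = "chr1", start = 4e5, end = 5e5, group = "PILO",
                    fold_change = 8)
  ls <- methylation_landscape(g, eff)
  tags2 <- simulate_capture_tags(g, ls, cfg)
  t2 <- tags2[tags2$sample == "PILO_1", ]
  inside <- mean(t2$pos5 >= 4e5 & t2$pos5 < 5e5)
  # expected fraction: 8w/(8w + rest) with w = 0.1 of the genome
  expect_equal(inside, 8 * 0.1 / (8 * 0.1 + 0.9), tolerance = 0.05)
  ctrl2 <- tags2[tags2$sample == "CTRL_1", ]
  expect_equal(mean(ctrl2$pos5 >= 4e5 & ctrl2$pos5 < 5e5), 0.1, tolerance = 0.05)
})

test_that("tag totals are Poisson at depth and duplicates appear at the set rate", {
  g <- generate_toy_genome(1, 1e6, 5, 5, seed = 3)
  cfg <- simulation_config(seed = 5, n_samples = c(CTRL = 1, PILO = 1),
                           depth = 5e4, duplicate_rate = 0.1)
  tags <- simulate_capture_tags(g, methylation_landscape(g), cfg)
  n <- table(tags$sample)
  expect_true(all(abs(n - cfg$depth) < 5 * sqrt(cfg$depth)))
  dedup <- deduplicate_tags(tags)
  removed <- 1 - nrow(dedup) / nrow(tags)
  # injected copies plus a small natural collision rate (~n / (2 * 2L) = 0.0125)
  expect_gt(removed, 0.095)
  expect_lt(removed, 0.13)
  # determinism
  tags_again <- simulate_capture_tags(g, methylation_landscape(g), cfg)
  expect_identical(tags, tags_again)
})

test_that("spared chromosome rejects effects; landscape validates inputs", {
  g <- generate_toy_genome(2, 5e5, 10, 10, seed = 4)
  eff <- data.frame(chrom = "chr2", start = 0, end = 100, group = "PILO",
                    fold_change = 4)
  expect_error(methylation_landscape(g, eff), "spared")
  bad <- data.frame(chrom = "chr1", start = 0, end = 100, group = "PILO",
                    fold_change = -1)
  expect_error(methylation_landscape(g, bad))
  out <- data.frame(chrom = "chr1", start = 0, end = 1e7, group = "PILO",
                    fold_change = 2)
  expect_error(methylation_landscape(g, out), "bounds")
  rl <- random_landscape(g, n_effects = 25, seed = 6)
  expect_false(any(rl$effects$chrom == "chr2"))
  expect_true(all(rl$effects$fold_change > 0))
})

test_that("expression counts couple inversely to planted methylation", {
  g <- generate_toy_genome(1, 2e6, 60, 40, seed = 8)
  ls <- random_landscape(g, n_effects = 20, feature_weight = 1, seed = 9)
  cfg <- simulation_config(seed = 10, n_samples = c(CTRL = 10, PILO = 10),
                           depth = 1e6, nb_dispersion = 0.05, coupling = 1)
  m <- simulate_expression_counts(g, ls, cfg)
  grp <- attr(m, "groups")
  truth <- attr(m, "true_logfc")[, "PILO"]
  est <- log2((rowMeans(m[, grp == "PILO"]) + 0.5) /
                (rowMeans(m[, grp == "CTRL"]) + 0.5))
  hyper_genes <- names(truth)[truth < 0]
  expect_gt(length(hyper_genes), 0)
  expect_equal(mean(est[hyper_genes]), -1, tolerance = 0.2)
  null_genes <- names(truth)[truth == 0]
  expect_equal(mean(est[null_genes]), 0, tolerance = 0.1)
  # coupling 0 leaves group means equal in expectation
  cfg0 <- simulation_config(seed = 10, n_samples = c(CTRL = 10, PILO = 10),
                            depth = 1e6, nb_dispersion = 0.05, coupling = 0)
  m0 <- simulate_expression_counts(g, ls, cfg0)
  est0 <- log2((rowMeans(m0[, grp == "PILO"]) + 0.5) /
                 (rowMeans(m0[, grp == "CTRL"]) + 0.5))
  expect_equal(mean(est0), 0, tolerance = 0.05)
})

test_that("bisulfite clone simulation respects proportions and seed", {
  expect_equal(simulate_bisulfite_clones(rep(1, 10), 6, seed = 1),
               matrix(1L, 6, 10), ignore_attr = TRUE)
  expect_error(simulate_bisulfite_clones(c(0.5, 1.2), 6, seed = 1), "\\[0, 1\\]")
  m <- simulate_bisulfite_clones(rep(0.5, 8), 1000, seed = 2)
  expect_true(all(abs(colMeans(m) - 0.5) < 0.05))
  expect_equal(nrow(simulate_bisulfite_clones(rep(0.3, 4), 6, seed = 3)), 6)
  expect_identical(simulate_bisulfite_clones(rep(0.3, 4), 6, seed = 3),
                   simulate_bisulfite_clones(rep(0.3, 4), 6, seed = 3))
})

test_that("qPCR plates recover planted folds through ddCt", {
  rel <- c(C1 = 1, C2 = 1, P1 = 0.25, P2 = 0.25)
  grp <- c(C1 = "CTRL", C2 = "CTRL", P1 = "PILO", P2 = "PILO")
  plate <- simulate_qpcr_plate(rel, grp, ct_noise_sd = 0, n_replicates = 3, seed = 1)
  res <- ddct_relative_expression(plate, control_group = "CTRL")
  expect_equal(res$per_sample$rq[res$per_sample$sample == "P1"], 0.25)
  expect_equal(res$group_summary$mean_rq[res$group_summary$group == "CTRL"], 1)
  expect_error(simulate_qpcr_plate(rel, grp, n_replicates = 2))
  # with noise, many replicates: recovery within a few percent
  plate2 <- simulate_qpcr_plate(rel, grp, ct_noise_sd = 0.1,
                                n_replicates = 1000, seed = 2)
  res2 <- ddct_relative_expression(plate2, control_group = "CTRL")
  expect_equal(res2$group_summary$mean_rq[res2$group_summary$group == "PILO"],
               0.25, tolerance = 0.01)
})
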