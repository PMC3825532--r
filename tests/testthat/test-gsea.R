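test_that("rank scores follow -log10(p) times fold-change sign with ties broken by id", {
  de <- data.frame(id = c("g1", "g2", "g3", "g4"),
                   logFC = c(1, -0.5, 2, 0),
                   p = c(0.01, 0.001, 1, 0.5))
  r <- rank_scores(de)
  expect_equal(r[["g1"]], 2)
  expect_equal(r[["g2"]], -3)
  expect_equal(r[["g3"]], 0)
  expect_equal(r[["g4"]], 0)
  expect_true(all(diff(unname(r)) <= 0))
  expect_equal(names(r)[2:3], c("g3", "g4"))  # tie at 0 broken by id
  de$p[1] <- 0
  expect_warning(r2 <- rank_scores(de), "capped")
  expect_equal(r2[["g1"]], 320)
})

test_that("methylation gene sets match a brute-force overlap oracle", {
  g <- tiny_genome()
  cat <- feature_catalog(g)
  set.seed(3)
  n <- 60
  dmr <- data.frame(chrom = sample(g$chromosomes$name, n, replace = TRUE),
                    start = sample.int(4e5, n))
  dmr$end <- dmr$start + sample.int(3000, n)
  dmr$logFC <- rnorm(n)
  dmr$p <- runif(n)^2
  suppressWarnings(sets <- build_methylation_gene_sets(dmr, cat, p_cut = 0.01))
  q <- dmr[dmr$p < 0.01, ]
  for (nm in names(sets)) {
    parts <- strsplit(nm, "_(?=[^_]+$)", perl = TRUE)[[1]]
    feat <- cat[[parts[1]]]
    sub <- if (parts[2] == "increased") q[q$logFC > 0, ] else q[q$logFC < 0, ]
    oracle <- sort(unique(feat$gene_id[vapply(seq_len(nrow(feat)), function(i) {
      any(sub$chrom == feat$chrom[i] &
            pmin(sub$end, feat$end[i]) - pmax(sub$start, feat$start[i]) >= 1)
    }, logical(1))]))
    expect_equal(sets[[nm]], oracle)
  }
  # p at or above the cutoff contributes nothing
  one <- dmr[1, ]; one$p <- 0.02; one$logFC <- 1
  expect_warning(s0 <- build_methylation_gene_sets(one, cat), "empty")
  expect_length(s0, 0)
})

test_that("TF promoter sets intersect promoters, map orthologs and apply size bounds", {
  g <- tiny_genome()
  cat <- feature_catalog(g)
  prom <- cat$promoter
  # one TF peak inside the first promoter, one in intergenic space far away
  chip <- list(TFA = data.frame(chrom = prom$chrom[1], start = prom$start[1],
                                end = prom$start[1] + 50))
  sets <- build_promoter_tf_gene_sets(chip, prom, size_bounds = c(1, 500))
  expect_equal(sets$TFA, prom$gene_id[1])
  # size bounds: a 1-gene set is dropped at min size 15
  sets2 <- build_promoter_tf_gene_sets(chip, prom, size_bounds = c(15, 500))
  expect_length(sets2, 0)
  # ortholog mapping drops unmapped genes and counts them
  map <- data.frame(from = "nonexistent", to = "HUMAN1")
  sets3 <- build_promoter_tf_gene_sets(chip, prom, ortholog_map = map,
                                       size_bounds = c(0, 500))
  expect_equal(attr(sets3, "n_unmapped"), 1L)
  # a catalog of 425 sets with 22 undersized retains 403
  prom_many <- data.frame(chrom = "chr1", start = seq(0, by = 100, length.out = 30))
  prom_many$end <- prom_many$start + 100
  prom_many$gene_id <- paste0("g", 1:30)
  big_chip <- c(
    lapply(1:403, function(i) data.frame(chrom = "chr1", start = 0, end = 3000)),
    lapply(1:22, function(i) data.frame(chrom = "chr1", start = 0, end = 100)))
  names(big_chip) <- paste0("tf", 1:425)
  kept <- build_promoter_tf_gene_sets(big_chip, prom_many, size_bounds = c(15, 500))
  expect_equal(attr(kept, "n_input"), 425L)
  expect_length(kept, 403)
})

test_that("enrichment score equals the cumulative-sum oracle and fgsea", {
  # top-ranked singleton at weight 0 scores ES = 1
  r <- setNames(c(5, 4, 3, 2, 1), paste0("g", 1:5))
  expect_equal(enrichment_score(r, "g1", weight = 0)$es, 1)
  expect_error(enrichment_score(r, paste0("g", 1:5)), "universe")
  expect_error(enrichment_score(r, "zzz"), "intersect")

  set.seed(17)
  ranked <- sort(setNames(rnorm(50), paste0("g", 1:50)), decreasing = TRUE)
  set_ids <- sample(names(ranked), 8)
  got <- enrichment_score(ranked, set_ids, weight = 1)
  # direct cumulative-sum oracle
  hit <- names(ranked) %in% set_ids
  inc <- ifelse(hit, abs(ranked) / sum(abs(ranked)[hit]), -1 / 42)
  run <- cumsum(inc)
  expect_equal(got$running, unname(run))
  expect_equal(got$es, unname(run[which.max(abs(run))]))
  expect_lte(abs(got$es), 1)
  # independent implementation: fgsea's statistic
  fg <- fgsea::calcGseaStat(unname(ranked), selectedStats = which(hit),
                            gseaParam = 1)
  expect_equal(got$es, fg, tolerance = 1e-8)
  # reversing the list negates ES at weight 0
  rev_ranked <- sort(-ranked, decreasing = TRUE)
  es_fwd <- enrichment_score(ranked, set_ids, weight = 0)$es
  es_rev <- enrichment_score(rev_ranked, set_ids, weight = 0)$es
  expect_equal(es_fwd, -es_rev, tolerance = 1e-10)
})

test_that("preranked GSEA is deterministic and calibrated on random sets", {
  set.seed(23)
  ranked <- sort(setNames(rnorm(300), paste0("g", 1:300)), decreasing = TRUE)
  sets <- lapply(1:60, function(i) sample(names(ranked), 15))
  names(sets) <- paste0("s", 1:60)
  res <- gsea_preranked(ranked, sets, n_perm = 200, seed = 7)
  res_again <- gsea_preranked(ranked, sets, n_perm = 200, seed = 7)
  expect_identical(res, res_again)
  expect_true(all(abs(res$es) <= 1))
  expect_true(all(sign(res$nes) == sign(res$es)))
  expect_true(all(res$fdr >= 0 & res$fdr <= 1))
  # null sets: nominal p roughly uniform
  frac <- mean(res$p < 0.05)
  expect_gte(frac, 0); expect_lte(frac, 0.12)

  # a planted set of top-ranked genes is detected, a random one is not
  planted <- list(top = names(ranked)[1:15], rnd = sample(names(ranked), 15))
  res2 <- gsea_preranked(ranked, planted, n_perm = 500, seed = 11)
  expect_gt(res2$es[res2$set == "top"], 0)
  expect_lt(res2$fdr[res2$set == "top"], 0.05)
  expect_gt(res2$fdr[res2$set == "rnd"], 0.25)
})

test_that("permutation p values are invariant to monotone rescaling at weight 0", {
  set.seed(29)
  ranked <- sort(setNames(rnorm(100), paste0("g", 1:100)), decreasing = TRUE)
  sets <- list(a = sample(names(ranked), 10), b = names(ranked)[1:10])
  r1 <- gsea_preranked(ranked, sets, n_perm = 200, seed = 3, weight = 0)
  rescaled <- sort(setNames(ranked * 7 + sign(ranked) * 2, names(ranked)),
                   decreasing = TRUE)
  r2 <- gsea_preranked(rescaled, sets, n_perm = 200, seed = 3, weight = 0)
  expect_equal(r1$p, r2$p)
  expect_equal(r1$es, r2$es)
})
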