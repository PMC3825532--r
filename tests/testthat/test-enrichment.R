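study_tab <- read.delim(system.file("extdata", "study_feature_contingency.tsv",
                                 package = "dmrcap"))

test_that("Fisher exact p: balanced tables, study row, and fisher.test oracle", {
  expect_equal(fisher_exact_two_sided(c(10, 10, 10, 10)), 1)
  expect_equal(fisher_exact_two_sided(c(3, 2, 1, 4)),
               fisher.test(matrix(c(3, 2, 1, 4), 2, 2, byrow = TRUE))$p.value)
  cgi <- unlist(study_tab[study_tab$feature == "CGI", 2:5])
  expect_equal(fisher_exact_two_sided(cgi), 9.7e-22, tolerance = 0.05)
  # zero margin convention
  expect_equal(fisher_exact_two_sided(c(0, 0, 3, 4)), 1)
})

test_that("Fisher exact p equals full enumeration for all small tables", {
  # exhaustive sweep over every 2x2 table with total <= 14
  for (n in 2:14) {
    parts <- expand.grid(a = 0:n, b = 0:n, c = 0:n)
    parts <- parts[rowSums(parts) <= n, ]
    parts$d <- n - rowSums(parts)
    for (i in seq_len(nrow(parts))) {
      tab <- unlist(parts[i, ])
      expect_equal(fisher_exact_two_sided(tab),
                   fisher.test(matrix(tab, 2, 2, byrow = TRUE))$p.value,
                   tolerance = 1e-9)
    }
  }
})

test_that("conditional-ML log2 odds ratio and exact CI match the fisher.test oracle", {
  expect_equal(log2_odds_ratio_ci(c(10, 10, 10, 10))[["log2_or"]], 0,
               tolerance = 1e-8)
  set.seed(5)
  for (i in 1:25) {
    tab <- rmultinom(1, sample(40:400, 1), runif(4, 0.05, 1))[, 1]
    if (any(colSums(matrix(tab, 2)) == 0) || any(rowSums(matrix(tab, 2)) == 0)) next
    got <- log2_odds_ratio_ci(tab)
    ft <- fisher.test(matrix(tab, 2, 2, byrow = TRUE))
    if (all(tab > 0)) {
      expect_equal(got[["log2_or"]], log2(ft$estimate[[1]]), tolerance = 1e-3)
    }
    expect_equal(got[["ci_low"]], log2(ft$conf.int[1]), tolerance = 2e-3)
    expect_equal(got[["ci_high"]], log2(ft$conf.int[2]), tolerance = 2e-3)
  }
})

test_that("odds ratio handles zero cells via Haldane correction and rejects zero margins", {
  got <- log2_odds_ratio_ci(c(0, 10, 5, 5))
  expect_equal(got[["log2_or"]], log2((0.5 / 10.5) / (5.5 / 5.5)), tolerance = 1e-9)
  expect_equal(got[["ci_low"]], -Inf)
  expect_error(log2_odds_ratio_ci(c(0, 0, 5, 5)), "margin")
  # asymptotic agreement with the sample OR when all cells are large
  big <- c(831, 621, 510, 611)
  expect_lt(abs(log2_odds_ratio_ci(big)[["log2_or"]] -
                  log2(831 * 611 / (621 * 510))), 0.01)
  # Woolf alternative stays close for large cells
  expect_equal(log2_odds_ratio_ci(big, method = "woolf")[["log2_or"]],
               log2(831 * 611 / (621 * 510)), tolerance = 1e-9)
})

test_that("swapping hyper and hypo roles negates log2 OR and preserves p", {
  tab <- c(148, 1304, 17, 1104)
  swapped <- c(17, 1104, 148, 1304)
  expect_equal(log2_odds_ratio_ci(tab)[["log2_or"]],
               -log2_odds_ratio_ci(swapped)[["log2_or"]], tolerance = 1e-8)
  expect_equal(fisher_exact_two_sided(tab), fisher_exact_two_sided(swapped),
               tolerance = 1e-12)
})

test_that("contingency construction conserves totals and flags empty inputs", {
  hyper <- random_intervals(120, seed = 1)
  hypo <- random_intervals(80, seed = 2)
  feat <- random_intervals(30, seed = 3)
  tab <- build_contingency(hyper, hypo, feat)
  expect_equal(tab[["a"]] + tab[["b"]], 120)
  expect_equal(tab[["c"]] + tab[["d"]], 80)
  all_ov <- build_contingency(hyper, hypo, intervals_df(c("chr1", "chr2"),
                                                        c(0, 0), c(2e4, 2e4)))
  expect_equal(all_ov[["b"]], 0); expect_equal(all_ov[["d"]], 0)
  expect_error(build_contingency(hyper[0, ], hypo, feat), "empty")
})

test_that("uniform placement gives overlap fractions near the feature genome share", {
  set.seed(9)
  L <- 1e6
  feat <- data.frame(chrom = "chr1", start = seq(0, L - 1e4, by = 5e4))
  feat$end <- feat$start + 1e4  # 20% of the genome
  mk <- function(n) {
    s <- sample.int(L - 100, n)
    data.frame(chrom = "chr1", start = s, end = s + 100)
  }
  tab <- build_contingency(mk(2000), mk(2000), feat)
  expect_lt(abs(tab[["a"]] / 2000 - 0.2), 0.05)
  expect_lt(abs(tab[["c"]] / 2000 - 0.2), 0.05)
  expect_lt(abs(log2_odds_ratio_ci(tab)[["log2_or"]]), 0.3)
})

test_that("background enrichment flags feature-concentrated hypermethylation", {
  set.seed(13)
  feat <- data.frame(chrom = "chr1", start = seq(0, 9e5, by = 1e5))
  feat$end <- feat$start + 2e4  # 10 islands
  inside <- feat[sample.int(10, 150, replace = TRUE), ]
  inside$start <- inside$start + sample.int(1e4, 150)
  inside$end <- inside$start + 500
  outside <- data.frame(chrom = "chr1", start = sample.int(9e5, 300))
  outside$end <- outside$start + 500
  res <- background_frequency_enrichment(
    hyper_regions = inside, hypo_regions = outside[1:100, ],
    nondiff_regions = outside[101:300, ], features = list(feat = feat))
  hyper_row <- res[res$direction == "hyper", ]
  expect_gt(hyper_row$log2_or, 0)
  expect_lt(hyper_row$p, 0.05)
  expect_error(background_frequency_enrichment(inside[0, ], outside, outside,
                                               list(feat = feat)), "direction")
  expect_error(background_frequency_enrichment(inside, outside, outside[0, ],
                                               list(feat = feat)), "background")
})
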