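test_that("tag counting respects half-open bounds and matches a per-tag scan", {
  chrlen <- c(chr1 = 1e4)
  regions <- intervals_df("chr1", 1000, 2000)
  tags <- make_tags("chr1", c(1100, 1500, 1900, 500, 3000), "+", "s1")
  m <- count_tags_per_region(regions, tags, chrlen, shift = 0)
  expect_equal(as.integer(m), 3L)
  # shifted position exactly at end is not counted (half-open)
  edge <- make_tags("chr1", c(2000 - 75, 1999 - 75), "+", "s1")
  m2 <- count_tags_per_region(regions, edge, chrlen, shift = 75)
  expect_equal(as.integer(m2), 1L)
  # random placement equals the brute-force scan oracle, per sample
  set.seed(3)
  regs <- data.frame(chrom = "chr1", start = c(0, 3000, 7000),
                     end = c(2000, 5000, 9000))
  rnd <- make_tags("chr1", sample.int(1e4, 2000, replace = TRUE),
                   sample(c("+", "-"), 2000, TRUE),
                   sample(c("a", "b"), 2000, TRUE))
  m3 <- count_tags_per_region(regs, rnd, chrlen, shift = 75)
  pos <- ifelse(rnd$strand == "+", rnd$pos5 + 75, rnd$pos5 - 75)
  pos <- pmin(pmax(pos, 0), 1e4 - 1)
  for (i in 1:3) for (s in c("a", "b")) {
    expect_equal(m3[i, s],
                 sum(pos >= regs$start[i] & pos < regs$end[i] & rnd$sample == s),
                 ignore_attr = TRUE)
  }
  # overlapping regions are ambiguous
  expect_error(count_tags_per_region(intervals_df("chr1", c(0, 50), c(100, 150)),
                                     tags, chrlen), "overlap")
})

test_that("centile filter uses linear interpolation and keeps ties", {
  m <- matrix(c(1, 2, 3, 4), 4, 1, dimnames = list(paste0("r", 1:4), "s1"))
  kept <- centile_filter(cbind(m, 0), 50)  # sums 1,2,3,4; threshold 2.5
  expect_equal(rownames(kept), c("r3", "r4"))
  expect_equal(nrow(centile_filter(cbind(m, 0), 0)), 4)
  tied <- matrix(5, 4, 2, dimnames = list(paste0("r", 1:4), c("a", "b")))
  expect_equal(nrow(centile_filter(tied, 50)), 4)
  expect_error(centile_filter(tied[0, , drop = FALSE], 50), "empty")
})

test_that("TMM factors are 1 for identical or depth-scaled columns and match edgeR", {
  m <- matrix(rpois(2000, 50), 500, 4,
              dimnames = list(NULL, paste0("s", 1:4)))
  expect_equal(unname(tmm_factors(cbind(s1 = m[, 1], s2 = m[, 1]))), c(1, 1))
  doubled <- cbind(A = m[, 1], B = 2L * m[, 1])
  expect_equal(unname(tmm_factors(doubled)), c(1, 1), tolerance = 1e-8)
  # composition bias: 5% of rows 100-fold inflated in one sample
  set.seed(11)
  biased <- m
  inflate <- sample.int(500, 25)
  biased[inflate, 1] <- biased[inflate, 1] * 100L
  f <- tmm_factors(biased)
  # composition bias: the inflated sample's factor drops below 1 so its
  # effective library absorbs the inflated rows
  expect_lt(f[["s1"]], 1)
  # edgeR breaks rank ties differently in the trim; agreement is to ~0.1%
  ref <- edgeR::calcNormFactors(biased, method = "TMM")
  expect_equal(unname(f), unname(ref), tolerance = 0.005)
  expect_error(tmm_factors(cbind(a = rep(0L, 5), b = 1:5)), "all-zero")
})

test_that("dispersion estimation recovers the simulation truth", {
  set.seed(21)
  m <- null_count_matrix(2000, c(5, 5), mu = 50, phi = 0.2, seed = 21)
  grp <- attr(m, "groups")
  d <- estimate_dispersions(m, grp, norm_factors = rep(1, 10))
  expect_gt(d$common, 0.15)
  expect_lt(d$common, 0.25)
  # Poisson data: near-zero dispersion
  mp <- matrix(rpois(2000 * 10, 50), 2000, 10,
               dimnames = list(paste0("r", 1:2000), paste0("s", 1:10)))
  dp <- estimate_dispersions(mp, grp, norm_factors = rep(1, 10))
  expect_lt(dp$common, 0.05)
  # infinite prior collapses tagwise onto common
  dinf <- estimate_dispersions(m, grp, norm_factors = rep(1, 10), prior_df = Inf)
  expect_true(all(dinf$tagwise == dinf$common))
  # finite prior shrinks toward common: tagwise spread is bounded
  expect_lt(sd(d$tagwise), 0.25)
  expect_error(estimate_dispersions(m[, c(1, 6)], grp[c(1, 6)]), "degrees of freedom")
})

test_that("exact NB test: identical groups give logFC 0 and p 1", {
  m <- cbind(a1 = c(10L, 25L), a2 = c(10L, 25L), b1 = c(10L, 25L), b2 = c(10L, 25L))
  rownames(m) <- c("r1", "r2")
  res <- nb_exact_test(m, factor(c("A", "A", "B", "B")), dispersions = 0.1,
                       norm_factors = rep(1, 4))
  expect_equal(res$logFC, c(0, 0))
  expect_equal(res$p, c(1, 1))
})

test_that("exact NB test at dispersion 0 equals binomial enumeration on small totals", {
  # oracle: conditional split of total z between groups is Binomial(z, nA/n)
  oracle_p <- function(za, z, na, nb) {
    pr <- dbinom(0:z, z, na / (na + nb))
    sum(pr[pr <= pr[za + 1] * (1 + 1e-8)])
  }
  set.seed(31)
  for (trial in 1:20) {
    na <- sample(2:4, 1); nb <- sample(2:4, 1)
    z <- sample(5:30, 1); za <- sample(0:z, 1)
    row1 <- integer(na + nb)
    row1[1:na] <- as.integer(rmultinom(1, za, rep(1, na)))
    row1[(na + 1):(na + nb)] <- as.integer(rmultinom(1, z - za, rep(1, nb)))
    # filler row equalizes library sizes so pseudo-counts equal raw counts
    filler <- max(row1) + 10L - row1
    m <- rbind(r1 = row1, r2 = filler)
    colnames(m) <- paste0("s", seq_len(na + nb))
    grp <- factor(rep(c("A", "B"), c(na, nb)), levels = c("B", "A"))
    res <- nb_exact_test(m, grp, dispersions = 0, norm_factors = rep(1, na + nb))
    expect_equal(res$p[1], oracle_p(za, z, na, nb), tolerance = 1e-6)
  }
})

test_that("planted logFC is recovered and the null is calibrated", {
  set.seed(41)
  n_null <- 950; n_eff <- 50
  mu <- 500
  m <- rbind(
    matrix(rnbinom(n_null * 9, size = 1 / 0.05, mu = mu), n_null, 9),
    cbind(matrix(rnbinom(n_eff * 4, size = 1 / 0.05, mu = mu), n_eff, 4),
          matrix(rnbinom(n_eff * 5, size = 1 / 0.05, mu = mu / 2), n_eff, 5)))
  dimnames(m) <- list(paste0("r", seq_len(n_null + n_eff)), paste0("s", 1:9))
  grp <- factor(rep(c("CTRL", "PILO"), c(4, 5)), levels = c("CTRL", "PILO"))
  res <- nb_exact_test(m, grp, dispersions = 0.05, norm_factors = tmm_factors(m))
  eff_rows <- (n_null + 1):(n_null + n_eff)
  expect_equal(mean(res$logFC[eff_rows]), -1, tolerance = 0.12)
  frac <- mean(res$p[1:n_null] < 0.05)
  expect_gt(frac, 0.01); expect_lt(frac, 0.09)
  # significant planted rows dominate the top of the ranking
  expect_gt(mean(res$fdr[eff_rows] < 0.05), 0.8)
  # full cross-check against the reference implementation on the same data
  d <- edgeR::DGEList(m, group = grp)
  d <- edgeR::calcNormFactors(d)
  et <- edgeR::exactTest(d, dispersion = 0.05)
  expect_gt(cor(log10(res$p), log10(et$table$PValue)), 0.999)
  expect_equal(res$logFC, et$table$logFC, tolerance = 0.02)
})

test_that("scaling one sample's counts is absorbed by TMM normalization", {
  m <- null_count_matrix(400, c(3, 3), mu = 100, phi = 0.05, seed = 51)
  grp <- attr(m, "groups")
  res1 <- nb_exact_test(m, grp)
  m2 <- m; m2[, 1] <- m2[, 1] * 3L
  res2 <- nb_exact_test(m2, grp)
  # equalization to the median effective library keeps the pseudo-counts (and
  # hence p values) essentially unchanged when one sample's depth is scaled
  expect_equal(res2$p, res1$p, tolerance = 0.02)
  expect_equal(res2$logFC, res1$logFC, tolerance = 0.02)
  expect_equal(mean(res2$p < 0.05), mean(res1$p < 0.05), tolerance = 0.01)
})

test_that("BH adjustment matches p.adjust and never decreases p", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  set.seed(61)
  for (i in 1:5) {
    p <- runif(sample(1:50, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, p.adjust(p, "BH"))
    expect_true(all(adj >= p - 1e-12))
  }
})

test_that("z-score clustering separates planted groups and is order-invariant", {
  set.seed(71)
  base <- matrix(rnorm(100 * 6), 100, 6,
                 dimnames = list(paste0("r", 1:100), paste0("s", 1:6)))
  base[1:50, 4:6] <- base[1:50, 4:6] + 3
  cl <- zscore_cluster(base)
  split2 <- cutree(cl$col_hclust, k = 2)
  expect_equal(length(unique(split2[c("s1", "s2", "s3")])), 1)
  expect_equal(length(unique(split2[c("s4", "s5", "s6")])), 1)
  expect_false(split2[["s1"]] == split2[["s4"]])
  # permuting input columns leaves the tree topology unchanged
  cl2 <- zscore_cluster(base[, c(5, 3, 1, 6, 2, 4)])
  expect_equal(cl2$col_order, cl$col_order)
  expect_equal(cutree(cl2$col_hclust, 2), split2)
  # duplicated columns sit at distance zero
  dup <- cbind(base, s1b = base[, "s1"])
  cld <- zscore_cluster(dup)
  d <- as.matrix(dist(t(cld$zscores)))
  expect_equal(d["s1", "s1b"], 0)
  # constant rows are dropped with a warning
  cm <- rbind(base, rconst = rep(1, 6))
  expect_warning(zscore_cluster(cm), "constant")
})
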