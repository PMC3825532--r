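#' Null calibration and planted-effect recovery of the NB exact test
#'
#' Simulates a count matrix with the workflow's typical group sizes (4 vs 5):
#' \code{n_null} rows with no group effect plus \code{n_planted} rows whose
#' case-group mean is doubled (true log2 fold change +1), at a total depth of
#' \code{depth} counts per sample. Runs the full normalization, dispersion
#' estimation and exact-test path and reports the null fraction below 0.05
#' and the mean absolute error of the planted log fold changes.
#'
#' @param seed integer seed.
#' @param n_null,n_planted row counts.
#' @param depth expected total counts per sample.
#' @param phi true negative-binomial dispersion.
#' @param n_per_group samples per group (control, case).
#' @return list: \code{null_fraction_p05}, \code{planted_logfc_mean} (the
#'   recovery target is its closeness to +1), \code{planted_logfc_mae},
#'   \code{dispersion_common}, \code{results}.
#' @export
calibration_experiment <- function(seed, n_null = 2000, n_planted = 100,
                                   depth = 1e6, phi = 0.1,
                                   n_per_group = c(4, 5)) {
  set.seed(as.integer(seed))
  n_rows <- n_null + n_planted
  mu <- depth / n_rows
  n <- sum(n_per_group)
  ctl_cols <- seq_len(n_per_group[1])
  m <- matrix(stats::rnbinom(n_rows * n, size = 1 / phi, mu = mu), n_rows, n,
              dimnames = list(paste0("r", seq_len(n_rows)), paste0("s", seq_len(n))))
  if (n_planted > 0) {
    planted <- (n_null + 1):n_rows
    m[planted, -ctl_cols] <- stats::rnbinom(n_planted * n_per_group[2],
                                            size = 1 / phi, mu = 2 * mu)
  }
  grp <- factor(rep(c("CTRL", "CASE"), n_per_group), levels = c("CTRL", "CASE"))
  nf <- tmm_factors(m)
  disp <- estimate_dispersions(m, grp, nf)
  res <- nb_exact_test(m, grp, disp, nf)
  list(null_fraction_p05 = mean(res$p[seq_len(n_null)] < 0.05),
       planted_logfc_mean = if (n_planted > 0)
         mean(res$logFC[(n_null + 1):n_rows]) else NA_real_,
       planted_logfc_mae = if (n_planted > 0)
         mean(abs(res$logFC[(n_null + 1):n_rows] - 1)) else NA_real_,
       dispersion_common = disp$common,
       results = res)
}

#' Methylation-expression coupling experiment
#'
#' One full run of the workflow on synthetic data with inverse coupling
#' between gene-body methylation and expression: capture tags with planted
#' hyper-/hypomethylation effects concentrated on genes and CpG islands are
#' carried through region discovery, counting, filtering and the NB exact
#' test; the resulting DMRs build interval-derived gene sets which are tested
#' by preranked GSEA against the expression ranking, alongside a size-matched
#' random control set. The set of genes whose bodies gained methylation
#' should enrich among repressed genes (negative ES); the random set should
#' not.
#'
#' @param seed integer seed (stage seeds derive from it).
#' @param chrom_length,n_genes,n_cgis,n_effects toy genome / landscape sizing.
#' @param depth tags (and expression counts) per sample.
#' @param n_per_group samples per group (control, case).
#' @param n_perm GSEA permutations.
#' @return data.frame of GSEA results for the gene-body-increased set and the
#'   random control, with attributes \code{n_dmr} and \code{set_size}; NULL
#'   when the target set is empty in this run.
#' @export
coupling_experiment <- function(seed, chrom_length = 4e6, n_genes = 200,
                                n_cgis = 150, n_effects = 60, depth = 2e5,
                                n_per_group = c(5, 4), n_perm = 1000) {
  genome <- generate_toy_genome(1, chrom_length, n_genes, n_cgis,
                                seed = child_seed(seed, "genome"))
  landscape <- random_landscape(genome, "PILO", n_effects = n_effects,
                                feature_weight = 0.8,
                                seed = child_seed(seed, "landscape"))
  cfg <- simulation_config(seed = child_seed(seed, "tags"),
                           n_samples = c(CTRL = n_per_group[1],
                                         PILO = n_per_group[2]),
                           depth = depth)
  tags <- deduplicate_tags(simulate_capture_tags(genome, landscape, cfg))
  chrlen <- stats::setNames(genome$chromosomes$length, genome$chromosomes$name)

  cand <- pairwise_candidate_regions(tags, chrlen)
  regions <- merge_intervals(cand)
  if (nrow(regions) == 0) return(NULL)
  mat <- centile_filter(count_tags_per_region(regions, tags, chrlen), 50)
  grp <- factor(attr(tags, "groups")[colnames(mat)], levels = c("CTRL", "PILO"))
  dmr <- nb_exact_test(mat, grp)
  dmr_iv <- cbind(region_ids_to_intervals(dmr$id),
                  dmr[, c("logFC", "p", "fdr")])

  catalog <- feature_catalog(genome)
  sets <- suppressWarnings(build_methylation_gene_sets(dmr_iv, catalog))

  expr <- simulate_expression_counts(genome, landscape, cfg)
  egrp <- factor(attr(expr, "groups")[colnames(expr)], levels = c("CTRL", "PILO"))
  ede <- nb_exact_test(centile_filter(expr, 30), egrp)
  ranked <- rank_scores(ede)

  target <- intersect(sets[["gene_body_increased"]], names(ranked))
  if (length(target) == 0) return(NULL)
  set.seed(child_seed(seed, "random_set"))
  random_set <- sample(names(ranked), length(target))
  res <- gsea_preranked(ranked,
                        list(gene_body_increased = target,
                             random_control = random_set),
                        n_perm = n_perm, seed = child_seed(seed, "gsea"))
  attr(res, "n_dmr") <- sum(dmr$p < 0.01)
  attr(res, "set_size") <- length(target)
  res
}

#' Clustering recovery experiment
#'
#' Simulates a two-group count matrix (4 vs 5 samples) with planted
#' differential rows, selects the rows the exact test calls at p < 0.01,
#' normalizes them (log2 counts per million at TMM-corrected library sizes),
#' and asks whether the two-cluster cut of the column dendrogram reproduces
#' the group labels.
#'
#' @param seed integer seed.
#' @param n_null,n_diff row counts (defaults give well over 50 called rows).
#' @param mu baseline mean count; planted rows double it in the case group.
#' @param phi negative-binomial dispersion.
#' @return list: \code{recovered} (logical), \code{n_significant}.
#' @export
cluster_recovery_experiment <- function(seed, n_null = 400, n_diff = 80,
                                        mu = 200, phi = 0.1) {
  set.seed(as.integer(seed))
  n_per_group <- c(4, 5)
  n <- sum(n_per_group)
  n_rows <- n_null + n_diff
  m <- matrix(stats::rnbinom(n_rows * n, size = 1 / phi, mu = mu), n_rows, n,
              dimnames = list(paste0("r", seq_len(n_rows)),
                              paste0("s", seq_len(n))))
  case_cols <- (n_per_group[1] + 1):n
  diff_rows <- (n_null + 1):n_rows
  up <- seq_along(diff_rows) %% 2 == 0
  m[diff_rows[up], case_cols] <- stats::rnbinom(sum(up) * n_per_group[2],
                                                size = 1 / phi, mu = 2 * mu)
  m[diff_rows[!up], case_cols] <- stats::rnbinom(sum(!up) * n_per_group[2],
                                                 size = 1 / phi, mu = mu / 2)
  grp <- factor(rep(c("CTRL", "CASE"), n_per_group), levels = c("CTRL", "CASE"))
  nf <- tmm_factors(m)
  res <- nb_exact_test(m, grp, norm_factors = nf)
  sig <- res$id[res$p < 0.01]
  eff <- colSums(m) * nf
  logcpm <- log2(sweep(m[sig, , drop = FALSE] + 0.5, 2, eff / 1e6, `/`))
  cl <- zscore_cluster(logcpm)
  cut2 <- stats::cutree(cl$col_hclust, k = 2)
  labels <- stats::setNames(as.character(grp), colnames(m))[names(cut2)]
  recovered <- length(unique(cut2[labels == "CTRL"])) == 1 &&
    length(unique(cut2[labels == "CASE"])) == 1 &&
    cut2[match("CTRL", labels)] != cut2[match("CASE", labels)]
  list(recovered = recovered, n_significant = length(sig))
}
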