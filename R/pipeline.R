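#' Pipeline configuration
#'
#' Collects the thresholds of the methyl-capture workflow with their default
#' values: window-caller significance 1e-5, tag shift 75 bp, region
#' significance 0.01, methylation count filter at the 50th centile,
#' expression filter at the 30th, non-differential background at
#' -log10(p) < 0.25, GSEA significance FDR 0.25 with 1000 permutations.
#'
#' @param groups named character vector sample -> group label (two groups,
#'   first-sorted level is the control unless \code{control} is given).
#' @param control,case group labels for the differential contrast.
#' @param peak_p_cutoff,shift,region_p_cutoff,methyl_centile,expr_centile,nondiff_neglog10p,gsea_fdr,n_permutations,prior_df thresholds (see description).
#' @param seed integer seed; per-stage child seeds are derived from it by
#'   stable hashing of the stage name.
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(groups, control = NULL, case = NULL,
                            peak_p_cutoff = 1e-5, shift = 75,
                            region_p_cutoff = 0.01, methyl_centile = 50,
                            expr_centile = 30, nondiff_neglog10p = 0.25,
                            gsea_fdr = 0.25, n_permutations = 1000,
                            prior_df = 10, seed = 1) {
  stopifnot(!is.null(names(groups)), length(unique(groups)) == 2,
            peak_p_cutoff > 0, peak_p_cutoff < 1,
            region_p_cutoff > 0, region_p_cutoff < 1,
            methyl_centile >= 0, methyl_centile <= 100,
            expr_centile >= 0, expr_centile <= 100,
            shift >= 0, n_permutations >= 1)
  lev <- sort(unique(groups))
  if (is.null(control)) control <- lev[1]
  if (is.null(case)) case <- setdiff(lev, control)[1]
  if (any(table(groups) < 2)) stop("need >= 2 samples per group for testing")
  structure(list(groups = groups, control = control, case = case,
                 peak_p_cutoff = peak_p_cutoff, shift = shift,
                 region_p_cutoff = region_p_cutoff,
                 methyl_centile = methyl_centile, expr_centile = expr_centile,
                 nondiff_neglog10p = nondiff_neglog10p, gsea_fdr = gsea_fdr,
                 n_permutations = n_permutations, prior_df = prior_df,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Derive a stage-specific child seed from the global seed
#'
#' Stable string hash of the stage name folded with the global seed, kept
#' below 2^31 so it is a valid R integer.
#'
#' @param seed global integer seed.
#' @param stage stage name.
#' @return integer seed.
#' @export
child_seed <- function(seed, stage) {
  h <- 0
  for (v in utf8ToInt(stage)) h <- (h * 31 + v) %% 1000003
  as.integer((as.numeric(seed) * 1009 + h * 97) %% 2147483647)
}

#' Run the full methyl-capture differential workflow
#'
#' Executes region discovery over all ordered sample pairs, interval merging,
#' tag counting, centile filtering, TMM normalization, the shrunken
#' negative-binomial exact test with BH adjustment, feature-overlap
#' enrichment, and (when an expression matrix is supplied) rank-score
#' construction and preranked GSEA of the interval-derived methylation gene
#' sets. Writes TSV tables when \code{out_dir} is given and returns a run
#' report listing record counts, the parameters actually applied, the output
#' manifest, and accumulated warnings.
#'
#' @param tags multi-sample tag data.frame with a \code{groups} attribute or
#'   matching \code{config$groups}.
#' @param genome toy genome (or compatible annotation list).
#' @param config \code{\link{pipeline_config}}.
#' @param expression optional gene x sample count matrix for the coupling
#'   analysis.
#' @param out_dir optional output directory for TSV tables.
#' @return list of class \code{run_report}; component \code{tables} holds the
#'   DMR table, enrichment table and GSEA results.
#' @export
run_pipeline <- function(tags, genome, config, expression = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  chrlen <- stats::setNames(genome$chromosomes$length, genome$chromosomes$name)
  warns <- character(0)
  note <- function(...) warns <<- c(warns, paste0(...))
  stages <- character(0)
  counts <- list()
  run_stage <- function(name, expr) {
    stages <<- c(stages, name)
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  tags <- run_stage("deduplicate", deduplicate_tags(tags))
  counts$tags_after_dedup <- nrow(tags)

  cand <- run_stage("pairwise_regions", pairwise_candidate_regions(
    tags, chrlen, shift = config$shift, p_cutoff = config$peak_p_cutoff))
  counts$pairwise_comparisons <- attr(cand, "n_comparisons")
  counts$candidate_regions <- nrow(cand)

  regions <- run_stage("merge", merge_intervals(cand))
  counts$merged_regions <- nrow(regions)
  if (nrow(regions) == 0) stop("pipeline stage 'merge' failed: no candidate regions")

  mat <- run_stage("count", count_tags_per_region(regions, tags, chrlen,
                                                  shift = config$shift))
  mat <- run_stage("centile_filter", centile_filter(mat, config$methyl_centile))
  counts$regions_after_filter <- nrow(mat)

  grp <- factor(config$groups[colnames(mat)],
                levels = c(config$control, config$case))
  de <- run_stage("differential", {
    nf <- tmm_factors(mat)
    disp <- estimate_dispersions(mat, grp, nf, prior_df = config$prior_df)
    nb_exact_test(mat, grp, disp, nf)
  })
  de$chrom <- regions$chrom[match(de$id, paste0(
    regions$chrom, ":", format(regions$start, scientific = FALSE, trim = TRUE),
    "-", format(regions$end, scientific = FALSE, trim = TRUE)))]
  dmr_iv <- cbind(region_ids_to_intervals(de$id), de[, c("logFC", "p", "fdr")])
  counts$dmr_significant <- sum(de$p < config$region_p_cutoff)

  hyper <- dmr_iv[dmr_iv$p < config$region_p_cutoff & dmr_iv$logFC > 0, , drop = FALSE]
  hypo <- dmr_iv[dmr_iv$p < config$region_p_cutoff & dmr_iv$logFC < 0, , drop = FALSE]
  catalog <- feature_catalog(genome)
  enrich <- run_stage("feature_enrichment", {
    if (nrow(hyper) == 0 || nrow(hypo) == 0) {
      note("feature enrichment skipped: a direction has no significant regions")
      NULL
    } else {
      feature_enrichment_table(hyper, hypo, catalog)
    }
  })

  gsea <- NULL
  if (!is.null(expression)) {
    gsea <- run_stage("gsea", {
      egrp <- factor(attr(expression, "groups")[colnames(expression)],
                     levels = c(config$control, config$case))
      emat <- centile_filter(expression, config$expr_centile)
      ede <- nb_exact_test(emat, egrp)
      ranked <- rank_scores(ede)
      sets <- withCallingHandlers(
        build_methylation_gene_sets(dmr_iv, catalog, config$region_p_cutoff),
        warning = function(w) { note(conditionMessage(w)); invokeRestart("muffleWarning") })
      sets <- lapply(sets, intersect, names(ranked))
      sets <- sets[lengths(sets) > 0]
      if (length(sets) == 0) {
        note("GSEA skipped: no non-empty methylation gene sets")
        NULL
      } else {
        res <- gsea_preranked(ranked, sets,
                              n_perm = config$n_permutations,
                              seed = child_seed(config$seed, "gsea"))
        attr(res, "expression_de") <- ede
        res
      }
    })
    counts$expression_de <- if (!is.null(gsea))
      sum(attr(gsea, "expression_de")$p < config$region_p_cutoff) else NA_integer_
  }

  manifest <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(df, name) {
      path <- file.path(out_dir, name)
      utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
      manifest <<- c(manifest, path)
    }
    wr(dmr_iv, "dmr_table.tsv")
    if (!is.null(enrich)) wr(enrich, "feature_enrichment.tsv")
    if (!is.null(gsea)) {
      wr(gsea, "gsea_results.tsv")
      wr(attr(gsea, "expression_de"), "expression_de.tsv")
    }
    stopifnot(all(file.exists(manifest)))
  }

  structure(list(stages = stages, counts = counts,
                 params = config, files = manifest, warnings = warns,
                 tables = list(dmr = dmr_iv, enrichment = enrich, gsea = gsea)),
            class = "run_report")
}

# "chr1:100-200" ids back to an interval data.frame
region_ids_to_intervals <- function(ids) {
  parts <- regmatches(ids, regexec("^(.+):([0-9]+)-([0-9]+)$", ids))
  data.frame(chrom = vapply(parts, `[`, character(1), 2),
             start = as.numeric(vapply(parts, `[`, character(1), 3)),
             end = as.numeric(vapply(parts, `[`, character(1), 4)),
             stringsAsFactors = FALSE)
}

#' @export
print.run_report <- function(x, ...) {
  cat("methyl-capture pipeline run\n")
  cat("  stages: ", paste(x$stages, collapse = " -> "), "\n", sep = "")
  for (nm in names(x$counts)) cat(sprintf("  %-24s %s\n", nm, x$counts[[nm]]))
  cat("  thresholds: peak p < ", x$params$peak_p_cutoff,
      ", shift ", x$params$shift, " bp, region p < ", x$params$region_p_cutoff,
      ", centiles ", x$params$methyl_centile, "/", x$params$expr_centile,
      "\n", sep = "")
  if (length(x$files)) cat("  outputs:", length(x$files), "file(s)\n")
  if (length(x$warnings)) cat("  warnings:", length(x$warnings), "\n")
  invisible(x)
}
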