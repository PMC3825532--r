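#' Rank scores from differential results
#'
#' Score = -log10(p) times the sign of the log fold change, so upregulated
#' genes rank positive. p values of zero are capped at \code{max_score} with a
#' warning. The returned vector is sorted descending with a deterministic
#' lexicographic tie-break on the gene id.
#'
#' @param de data.frame with columns id, logFC, p.
#' @param max_score cap for -log10(p) when p underflows to zero.
#' @return named numeric vector, sorted descending.
#' @export
rank_scores <- function(de, max_score = 320) {
  stopifnot(all(c("id", "logFC", "p") %in% names(de)),
            !anyDuplicated(de$id), all(is.finite(de$logFC)))
  if (any(de$p == 0)) {
    warning(sum(de$p == 0), " p value(s) of zero capped at -log10 p = ", max_score)
  }
  s <- pmin(-log10(pmax(de$p, 10^(-max_score))), max_score) * sign(de$logFC)
  ord <- order(-s, de$id)
  stats::setNames(s[ord], de$id[ord])
}

#' Interval-derived methylation gene sets
#'
#' For each genic feature (gene body, TSS, promoter, exon, intron) and each
#' methylation direction, collects the genes whose feature instance overlaps
#' (>= 1 bp) a differentially methylated region passing the p-value cutoff.
#' Set names are e.g. \code{"gene_body_increased"}. Empty sets are dropped
#' with a warning.
#'
#' @param dmr data.frame of regions with columns chrom, start, end, logFC, p.
#' @param catalog feature catalog (genic entries must carry gene_id).
#' @param p_cut region p-value cutoff (default 0.01).
#' @return named list of character vectors of gene ids.
#' @export
build_methylation_gene_sets <- function(dmr, catalog, p_cut = 0.01) {
  q <- dmr[dmr$p < p_cut, , drop = FALSE]
  feats <- c("gene_body", "tss", "promoter", "exon", "intron")
  sets <- list()
  for (dir in c("increased", "decreased")) {
    sub <- if (dir == "increased") q[q$logFC > 0, , drop = FALSE]
           else q[q$logFC < 0, , drop = FALSE]
    for (f in feats) {
      fc <- catalog[[f]]
      nm <- paste(f, dir, sep = "_")
      if (nrow(sub) == 0 || nrow(fc) == 0) { sets[[nm]] <- character(0); next }
      hits <- GenomicRanges::findOverlaps(as_granges0(fc), as_granges0(sub),
                                          minoverlap = 1L)
      sets[[nm]] <- sort(unique(fc$gene_id[S4Vectors::queryHits(hits)]))
    }
  }
  empty <- lengths(sets) == 0
  if (any(empty)) {
    warning("dropping empty gene set(s): ", paste(names(sets)[empty], collapse = ", "))
    sets <- sets[!empty]
  }
  sets
}

#' Promoter-intersection gene sets from ChIP intervals
#'
#' One set per transcription-factor track: genes whose promoter overlaps a
#' ChIP interval, mapped to the ranked-list id space through an ortholog
#' table. Sets outside the size bounds are excluded before GSEA.
#'
#' @param chip_intervals_by_tf named list of interval data.frames.
#' @param promoters promoter intervals with a gene_id column.
#' @param ortholog_map data.frame with columns \code{from}, \code{to} mapping
#'   annotation gene ids to ranked-list ids; NULL for identity.
#' @param size_bounds inclusive set-size bounds (default c(15, 500)).
#' @return named list of character vectors; the number of unmapped gene ids
#'   is attached as attribute \code{n_unmapped}.
#' @export
build_promoter_tf_gene_sets <- function(chip_intervals_by_tf, promoters,
                                        ortholog_map = NULL,
                                        size_bounds = c(15, 500)) {
  prom_gr <- as_granges0(promoters)
  n_unmapped <- 0L
  sets <- lapply(chip_intervals_by_tf, function(chip) {
    if (nrow(chip) == 0) return(character(0))
    hits <- GenomicRanges::findOverlaps(prom_gr, as_granges0(chip), minoverlap = 1L)
    genes <- unique(promoters$gene_id[S4Vectors::queryHits(hits)])
    if (!is.null(ortholog_map)) {
      mapped <- ortholog_map$to[match(genes, ortholog_map$from)]
      n_unmapped <<- n_unmapped + sum(is.na(mapped))
      genes <- mapped[!is.na(mapped)]
    }
    sort(unique(genes))
  })
  keep <- lengths(sets) >= size_bounds[1] & lengths(sets) <= size_bounds[2]
  out <- sets[keep]
  attr(out, "n_unmapped") <- n_unmapped
  attr(out, "n_input") <- length(sets)
  out
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' The standard preranked GSEA running sum: walking down the ranked list,
#' hits increment by |score|^weight normalized by the set's total, misses
#' decrement by 1/(N - Nh); ES is the signed maximum deviation.
#'
#' @param ranked named numeric vector sorted descending (see
#'   \code{\link{rank_scores}}).
#' @param gene_set character vector of member ids.
#' @param weight score exponent (default 1; 0 = classic KS).
#' @return list: \code{es}, \code{running} (the running-sum profile).
#' @export
enrichment_score <- function(ranked, gene_set, weight = 1) {
  hit <- names(ranked) %in% gene_set
  nh <- sum(hit)
  if (nh == 0) stop("gene set does not intersect the ranked universe")
  if (nh == length(ranked)) stop("gene set covers the whole universe")
  es_from_hits(ranked, hit, weight)
}

es_from_hits <- function(ranked, hit, weight) {
  n <- length(ranked)
  w <- abs(ranked)^weight
  denom <- sum(w[hit])
  step <- rep(-1 / (n - sum(hit)), n)
  step[hit] <- if (denom == 0) 1 / sum(hit) else w[hit] / denom
  running <- cumsum(step)
  list(es = running[which.max(abs(running))], running = running)
}

#' Preranked GSEA with gene-set permutations
#'
#' For each set, the null distribution of ES comes from \code{n_perm} random
#' draws of equally sized sets from the universe. NES divides ES by the mean
#' |null ES| of matching sign; the nominal p is the matching-sign null tail;
#' the FDR q compares each NES against the pooled sign-matched null NES
#' distribution, in the manner of the standard GSEA procedure. Deterministic
#' for a fixed seed.
#'
#' @param ranked named numeric vector sorted descending.
#' @param gene_sets named list of character vectors.
#' @param n_perm number of gene-set permutations (default 1000).
#' @param seed integer seed.
#' @param weight score exponent.
#' @return data.frame: set, size, es, nes, p, fdr.
#' @export
gsea_preranked <- function(ranked, gene_sets, n_perm = 1000, seed = 1, weight = 1) {
  stopifnot(n_perm >= 1, length(gene_sets) >= 1)
  set.seed(as.integer(seed))
  n <- length(ranked)
  ids <- names(ranked)
  sizes <- vapply(gene_sets, function(s) sum(ids %in% s), integer(1))

  es_obs <- vapply(names(gene_sets), function(nm) {
    enrichment_score(ranked, gene_sets[[nm]], weight)$es
  }, numeric(1))

  null_nes <- vector("list", length(gene_sets))
  nes <- p <- numeric(length(gene_sets))
  for (i in seq_along(gene_sets)) {
    k <- sizes[i]
    null_es <- vapply(seq_len(n_perm), function(b) {
      hit <- logical(n)
      hit[sample.int(n, k)] <- TRUE
      es_from_hits(ranked, hit, weight)$es
    }, numeric(1))
    mpos <- mean(null_es[null_es >= 0]); mneg <- mean(abs(null_es[null_es < 0]))
    norm1 <- function(e) {
      d <- if (e >= 0) mpos else mneg
      if (!is.finite(d) || d == 0) return(NA_real_)
      e / d
    }
    nes[i] <- norm1(es_obs[i])
    null_nes[[i]] <- vapply(null_es, norm1, numeric(1))
    same <- if (es_obs[i] >= 0) null_es[null_es >= 0] else null_es[null_es < 0]
    p[i] <- if (length(same) == 0) 1 / n_perm else
      (sum(abs(same) >= abs(es_obs[i])) + 1) / (length(same) + 1)
  }
  pool <- unlist(null_nes)
  fdr <- vapply(seq_along(gene_sets), function(i) {
    if (!is.finite(nes[i])) return(NA_real_)
    if (nes[i] >= 0) {
      num <- mean(pool[pool >= 0] >= nes[i])
      den <- mean(nes[nes >= 0] >= nes[i])
    } else {
      num <- mean(pool[pool < 0] <= nes[i])
      den <- mean(nes[nes < 0] <= nes[i])
    }
    if (!is.finite(num)) num <- 0
    min(1, if (den == 0) 1 else num / den)
  }, numeric(1))
  data.frame(set = names(gene_sets), size = sizes, es = es_obs, nes = nes,
             p = p, fdr = fdr, row.names = NULL, stringsAsFactors = FALSE)
}
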