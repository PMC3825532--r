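#' Simulation configuration
#'
#' Bundles and validates the knobs of the synthetic-data generator. The seed
#' fully determines all generator outputs.
#'
#' @param seed integer seed.
#' @param n_samples named integer vector: samples per group, first group is the
#'   reference/control. Default \code{c(CTRL = 5, PILO = 4)}, the group sizes
#'   of a typical small methyl-capture cohort.
#' @param depth expected tags (or expression counts) per sample.
#' @param duplicate_rate fraction of emitted tags that are resampled copies of
#'   other tags of the same sample, in [0, 1).
#' @param nb_dispersion negative-binomial dispersion of expression counts.
#' @param coupling expression log2 fold change applied to genes whose bodies
#'   carry hypermethylation effects (sign inverted, i.e. hypermethylated gene
#'   bodies are repressed by \code{coupling} log2 units; hypomethylated ones
#'   activated).
#' @return list of class \code{sim_config}.
#' @export
simulation_config <- function(seed, n_samples = c(CTRL = 5, PILO = 4),
                              depth = 5e4, duplicate_rate = 0.05,
                              nb_dispersion = 0.1, coupling = 1) {
  stopifnot(length(seed) == 1, is.finite(seed),
            length(n_samples) >= 2, all(n_samples >= 1),
            !is.null(names(n_samples)),
            depth > 0, duplicate_rate >= 0, duplicate_rate < 1,
            nb_dispersion >= 0, is.finite(coupling))
  structure(list(seed = as.integer(seed), n_samples = n_samples, depth = depth,
                 duplicate_rate = duplicate_rate, nb_dispersion = nb_dispersion,
                 coupling = coupling),
            class = "sim_config")
}

#' Generate a toy genome
#'
#' Places non-overlapping stranded genes (each with ordered, non-overlapping
#' exons) and CpG islands on one or more chromosomes. CGIs are placed both
#' inside gene bodies and in intergenic space. When the genome has at least
#' two chromosomes the last one is flagged "spared": the landscape generator
#' will put no differential-methylation effects on it, emulating the
#' X-chromosome sparing seen in capture data.
#'
#' @param n_chroms number of chromosomes.
#' @param chrom_length length of each chromosome in bp.
#' @param n_genes,n_cgis total genes / CpG islands to place.
#' @param seed integer seed; output is deterministic given the seed.
#' @param gene_length_range,cgi_length_range bp ranges to draw lengths from.
#' @param spare_last flag the last chromosome as spared (default when
#'   \code{n_chroms >= 2}).
#' @return list of class \code{toy_genome}: \code{chromosomes} (name, length),
#'   \code{genes} (gene_id, chrom, start, end, strand), \code{exons}
#'   (gene_id, chrom, start, end), \code{cgis}, \code{spared_chrom}.
#' @export
generate_toy_genome <- function(n_chroms, chrom_length, n_genes, n_cgis, seed,
                                gene_length_range = c(2000, 20000),
                                cgi_length_range = c(300, 1500),
                                spare_last = n_chroms >= 2) {
  set.seed(as.integer(seed))
  chroms <- data.frame(name = paste0("chr", seq_len(n_chroms)),
                       length = rep(chrom_length, n_chroms),
                       stringsAsFactors = FALSE)
  per_chrom <- tabulate(sample.int(n_chroms, n_genes, replace = TRUE), n_chroms)
  genes_list <- list(); exons_list <- list()
  gid <- 0
  for (i in seq_len(n_chroms)) {
    g <- per_chrom[i]
    if (g == 0) next
    lens <- round(stats::runif(g, gene_length_range[1], gene_length_range[2]))
    if (sum(lens) + g + 1 > chrom_length) {
      stop("genome too small: cannot place ", g, " genes of total length ",
           sum(lens), " bp on a ", chrom_length, " bp chromosome")
    }
    free <- chrom_length - sum(lens)
    # non-overlapping placement: split the free space into g+1 random gaps
    cuts <- sort(sample.int(free, g))
    gaps <- diff(c(0, cuts))
    starts <- cumsum(gaps) + cumsum(c(0, lens[-g]))
    strands <- sample(c("+", "-"), g, replace = TRUE)
    ids <- paste0("gene", gid + seq_len(g))
    gid <- gid + g
    genes_list[[i]] <- data.frame(gene_id = ids, chrom = chroms$name[i],
                                  start = starts, end = starts + lens,
                                  strand = strands, stringsAsFactors = FALSE)
    exons_list[[i]] <- do.call(rbind, lapply(seq_len(g), function(j) {
      make_exons(ids[j], chroms$name[i], starts[j], starts[j] + lens[j])
    }))
  }
  genes <- do.call(rbind, genes_list)
  exons <- do.call(rbind, exons_list)
  rownames(genes) <- rownames(exons) <- NULL

  if (n_cgis > 0) {
    cgi_len <- round(stats::runif(n_cgis, cgi_length_range[1], cgi_length_range[2]))
    in_gene <- stats::runif(n_cgis) < 0.7 & nrow(genes) > 0
    cgi <- lapply(seq_len(n_cgis), function(k) {
      L <- cgi_len[k]
      if (in_gene[k]) {
        g <- genes[sample.int(nrow(genes), 1), ]
        span <- g$end - g$start
        if (span <= L) { s <- g$start; L <- min(L, span) }
        else s <- g$start + sample.int(span - L, 1)
        data.frame(chrom = g$chrom, start = s, end = s + L)
      } else {
        ci <- sample.int(n_chroms, 1)
        s <- sample.int(chrom_length - L, 1)
        data.frame(chrom = chroms$name[ci], start = s, end = s + L)
      }
    })
    cgis <- do.call(rbind, cgi)
    cgis$cgi_id <- paste0("cgi", seq_len(n_cgis))
  } else {
    cgis <- data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
                       cgi_id = character(0))
  }
  structure(list(chromosomes = chroms, genes = genes, exons = exons, cgis = cgis,
                 spared_chrom = if (spare_last) chroms$name[n_chroms] else NA_character_),
            class = "toy_genome")
}

# cut a gene span into alternating exon/intron blocks; first and last block are
# exons, so every gene has >= 1 exon and introns are interior
make_exons <- function(gene_id, chrom, start, end) {
  span <- end - start
  n_ex <- sample.int(min(6, max(1, span %/% 400)), 1)
  if (n_ex == 1) {
    return(data.frame(gene_id = gene_id, chrom = chrom, start = start, end = end,
                      stringsAsFactors = FALSE))
  }
  n_blocks <- 2 * n_ex - 1
  cuts <- sort(sample.int(span - 1, n_blocks - 1))
  bounds <- c(0, cuts, span) + start
  idx <- seq(1, n_blocks, by = 2)  # odd blocks are exons
  data.frame(gene_id = gene_id, chrom = chrom,
             start = bounds[idx], end = bounds[idx + 1],
             stringsAsFactors = FALSE)
}

#' Construct a methylation landscape
#'
#' The landscape is a per-group relative capture density: a strictly positive
#' baseline (uniform over the genome) times a fold change over each effect
#' interval. Effects on the genome's spared chromosome are rejected.
#'
#' @param genome toy genome.
#' @param effects data.frame with columns chrom, start, end, group,
#'   fold_change (> 0): the capture-density multiplier over that interval for
#'   samples of that group. An optional \code{effect_id} column ties together
#'   rows describing the same physical interval in different groups (so a
#'   methylated region can be enriched in every group but more so in one);
#'   absent, each row gets its own id.
#' @param baseline baseline density (tags/bp, relative; positive).
#' @return list of class \code{methylation_landscape}.
#' @export
methylation_landscape <- function(genome, effects = NULL, baseline = 1) {
  stopifnot(baseline > 0)
  if (is.null(effects) || nrow(effects) == 0) {
    effects <- data.frame(chrom = character(0), start = numeric(0),
                          end = numeric(0), group = character(0),
                          fold_change = numeric(0), effect_id = integer(0))
  } else {
    if (is.null(effects$effect_id)) effects$effect_id <- seq_len(nrow(effects))
    stopifnot(all(effects$fold_change > 0))
    validate_intervals(effects)
    chrlen <- stats::setNames(genome$chromosomes$length, genome$chromosomes$name)
    if (any(effects$end > chrlen[effects$chrom])) {
      stop("effect interval outside chromosome bounds")
    }
    if (!is.na(genome$spared_chrom) && any(effects$chrom == genome$spared_chrom)) {
      stop("effects placed on spared chromosome ", genome$spared_chrom)
    }
  }
  structure(list(genome = genome, baseline = baseline, effects = effects),
            class = "methylation_landscape")
}

#' Draw a random group-structured methylation landscape
#'
#' Effect intervals are placed preferentially (weight \code{feature_weight})
#' on CpG islands or gene bodies, mirroring where capture signal concentrates,
#' and never on the spared chromosome. Every effect interval is a methylated
#' region enriched \code{base_enrichment}-fold over background in both groups
#' (methyl-capture pulls down methylated DNA in every sample); on top of
#' that, half the effects are hypermethylation (the case group's density is
#' further multiplied by a fold drawn from \code{fold_range}) and half
#' hypomethylation (the control group gets the extra fold). This keeps both
#' directions visible to an enrichment-over-background caller, as in real
#' capture data.
#'
#' @param genome toy genome.
#' @param case_group,control_group group labels (case carries the
#'   hypermethylation gains).
#' @param n_effects number of effect intervals (placed disjoint).
#' @param fold_range range of differential fold changes.
#' @param base_enrichment capture enrichment of methylated DNA over
#'   unmethylated background, applied to both groups.
#' @param effect_length_range bp range of effect interval lengths.
#' @param feature_weight probability that an effect is anchored on a CGI or
#'   gene body rather than placed uniformly.
#' @param seed integer seed.
#' @return a \code{methylation_landscape}; its effects carry a
#'   \code{direction} column ("hyper"/"hypo", case relative to control).
#' @export
random_landscape <- function(genome, case_group = "PILO",
                             control_group = "CTRL", n_effects = 30,
                             fold_range = c(4, 8), base_enrichment = 4,
                             effect_length_range = c(500, 2000),
                             feature_weight = 0.7, seed = 1) {
  set.seed(as.integer(seed))
  anchors <- rbind(genome$genes[, c("chrom", "start", "end")],
                   genome$cgis[, c("chrom", "start", "end")])
  if (!is.na(genome$spared_chrom)) {
    anchors <- anchors[anchors$chrom != genome$spared_chrom, , drop = FALSE]
  }
  ok_chroms <- genome$chromosomes[is.na(genome$spared_chrom) |
                                    genome$chromosomes$name != genome$spared_chrom, ,
                                  drop = FALSE]
  # effects are placed disjoint (rejection sampling): overlapping hyper and
  # hypo effects would cancel multiplicatively and blur the planted truth
  placed <- list()
  attempts <- 0
  while (length(placed) < n_effects && attempts < 200 * n_effects) {
    attempts <- attempts + 1
    L <- round(stats::runif(1, effect_length_range[1], effect_length_range[2]))
    cand <- if (stats::runif(1) < feature_weight && nrow(anchors) > 0) {
      a <- anchors[sample.int(nrow(anchors), 1), ]
      ci <- ok_chroms$length[match(a$chrom, ok_chroms$name)]
      s <- a$start + sample.int(max(1, a$end - a$start), 1) - 1
      s <- max(0, min(s, ci - L))
      data.frame(chrom = a$chrom, start = s, end = min(s + L, ci))
    } else {
      i <- sample.int(nrow(ok_chroms), 1)
      s <- sample.int(ok_chroms$length[i] - L, 1)
      data.frame(chrom = ok_chroms$name[i], start = s, end = s + L)
    }
    clash <- any(vapply(placed, function(p) {
      p$chrom == cand$chrom && pmin(p$end, cand$end) > pmax(p$start, cand$start)
    }, logical(1)))
    if (!clash) placed[[length(placed) + 1]] <- cand
  }
  if (length(placed) < n_effects) {
    stop("could not place ", n_effects, " disjoint effects; genome too small")
  }
  iv <- do.call(rbind, placed)
  fc <- stats::runif(n_effects, fold_range[1], fold_range[2])
  hypo <- seq_len(n_effects) > n_effects / 2
  case_rows <- data.frame(iv, group = case_group,
                          fold_change = base_enrichment * ifelse(hypo, 1, fc),
                          effect_id = seq_len(n_effects),
                          direction = ifelse(hypo, "hypo", "hyper"))
  ctrl_rows <- data.frame(iv, group = control_group,
                          fold_change = base_enrichment * ifelse(hypo, fc, 1),
                          effect_id = seq_len(n_effects),
                          direction = ifelse(hypo, "hypo", "hyper"))
  methylation_landscape(genome, rbind(case_rows, ctrl_rows))
}

# piecewise-constant density segments for one group: data.frame(chrom, start,
# end, weight) with weight = length * baseline * prod(fold changes covering it)
density_segments <- function(landscape, group) {
  genome <- landscape$genome
  eff <- landscape$effects
  eff <- eff[eff$group == group, , drop = FALSE]
  segs <- lapply(seq_len(nrow(genome$chromosomes)), function(i) {
    nm <- genome$chromosomes$name[i]
    L <- genome$chromosomes$length[i]
    e <- eff[eff$chrom == nm, , drop = FALSE]
    bounds <- sort(unique(c(0, L, e$start, e$end)))
    s <- bounds[-length(bounds)]; en <- bounds[-1]
    dens <- rep(landscape$baseline, length(s))
    for (j in seq_len(nrow(e))) {
      cover <- s >= e$start[j] & en <= e$end[j]
      dens[cover] <- dens[cover] * e$fold_change[j]
    }
    data.frame(chrom = nm, start = s, end = en, dens = dens)
  })
  segs <- do.call(rbind, segs)
  segs$weight <- segs$dens * (segs$end - segs$start)
  segs
}

#' Simulate methyl-capture tag alignments
#'
#' Per sample, the tag total is a Poisson draw at the configured depth; 5'
#' positions are drawn from the sample group's piecewise-constant capture
#' density, strands are uniform, and \code{duplicate_rate} of the emitted tags
#' are replaced by copies of other tags of the same sample (exact
#' chrom/position/strand collisions, which deduplication must remove).
#'
#' @param genome toy genome.
#' @param landscape methylation landscape consistent with the genome.
#' @param config \code{\link{simulation_config}}.
#' @return data.frame with columns chrom, pos5, strand, sample and attributes
#'   \code{groups} (named vector sample -> group).
#' @export
simulate_capture_tags <- function(genome, landscape, config) {
  set.seed(config$seed)
  groups <- rep(names(config$n_samples), config$n_samples)
  samples <- paste(groups, unlist(lapply(config$n_samples, seq_len)), sep = "_")
  out <- vector("list", length(samples))
  for (si in seq_along(samples)) {
    segs <- density_segments(landscape, groups[si])
    n <- stats::rpois(1, config$depth)
    seg_idx <- sample.int(nrow(segs), n, replace = TRUE, prob = segs$weight)
    width <- segs$end[seg_idx] - segs$start[seg_idx]
    pos <- segs$start[seg_idx] + floor(stats::runif(n) * width)
    tags <- data.frame(chrom = segs$chrom[seg_idx], pos5 = pos,
                       strand = sample(c("+", "-"), n, replace = TRUE),
                       sample = samples[si], stringsAsFactors = FALSE)
    ndup <- round(config$duplicate_rate * n)
    if (ndup > 0 && n > 1) {
      which_dup <- sample.int(n, ndup)
      src <- sample(setdiff(seq_len(n), which_dup), ndup, replace = TRUE)
      tags[which_dup, c("chrom", "pos5", "strand")] <-
        tags[src, c("chrom", "pos5", "strand")]
    }
    out[[si]] <- tags
  }
  tags <- do.call(rbind, out)
  rownames(tags) <- NULL
  attr(tags, "groups") <- stats::setNames(groups, samples)
  tags
}

#' Simulate expression counts coupled to gene-body methylation
#'
#' Gene baseline means are log-normal and scaled to the configured depth;
#' counts are negative binomial at \code{nb_dispersion}. A gene whose body
#' overlaps (>= 1 bp) a hypermethylation effect has its mean multiplied by
#' \code{2^-coupling} in the effect's group (repression); hypomethylation
#' effects act inversely. With \code{coupling = 0} all groups share the same
#' means.
#'
#' @inheritParams simulate_capture_tags
#' @return integer matrix genes x samples with a \code{groups} attribute; a
#'   \code{true_logfc} attribute records each gene's planted case-vs-control
#'   log2 fold change per non-reference group.
#' @export
simulate_expression_counts <- function(genome, landscape, config) {
  set.seed(config$seed + 1L)
  genes <- genome$genes
  ng <- nrow(genes)
  base_mu <- stats::rlnorm(ng, meanlog = 0, sdlog = 1)
  base_mu <- base_mu / sum(base_mu) * config$depth
  groups <- rep(names(config$n_samples), config$n_samples)
  samples <- paste(groups, unlist(lapply(config$n_samples, seq_len)), sep = "_")

  eff <- landscape$effects
  group_names <- names(config$n_samples)
  ref_group <- group_names[1]
  logfc <- matrix(0, ng, length(group_names),
                  dimnames = list(genes$gene_id, group_names))
  if (nrow(eff) > 0 && config$coupling != 0) {
    # per physical interval, each group's density multiplier vs the
    # reference group decides the methylation direction the gene sees
    iv <- eff[!duplicated(eff$effect_id), c("chrom", "start", "end", "effect_id")]
    mult <- function(id, grp) {
      row <- eff$effect_id == id & eff$group == grp
      if (any(row)) eff$fold_change[which(row)[1]] else 1
    }
    hits <- GenomicRanges::findOverlaps(
      as_granges0(genes[, c("chrom", "start", "end")]),
      as_granges0(iv[, c("chrom", "start", "end")]), minoverlap = 1L)
    net <- matrix(0, ng, length(group_names),
                  dimnames = list(genes$gene_id, group_names))
    for (h in seq_along(S4Vectors::queryHits(hits))) {
      g <- S4Vectors::queryHits(hits)[h]
      id <- iv$effect_id[S4Vectors::subjectHits(hits)[h]]
      for (grp in group_names) {
        net[g, grp] <- net[g, grp] + log2(mult(id, grp)) - log2(mult(id, ref_group))
      }
    }
    logfc <- -config$coupling * sign(net)
  }
  counts <- matrix(0L, ng, length(samples), dimnames = list(genes$gene_id, samples))
  for (si in seq_along(samples)) {
    mu <- base_mu * 2^logfc[, groups[si]]
    counts[, si] <- if (config$nb_dispersion < 1e-8) {
      stats::rpois(ng, mu)
    } else {
      stats::rnbinom(ng, size = 1 / config$nb_dispersion, mu = mu)
    }
  }
  attr(counts, "groups") <- stats::setNames(groups, samples)
  attr(counts, "true_logfc") <- logfc
  counts
}

#' Simulate bisulfite clone calls
#'
#' Independent Bernoulli methylation calls per clone and CpG.
#'
#' @param true_methylation vector of per-CpG methylation proportions in [0,1].
#' @param n_clones number of clones (rows); the downstream QC gate expects at
#'   least six per subject.
#' @param seed integer seed.
#' @return binary matrix clones x CpGs.
#' @export
simulate_bisulfite_clones <- function(true_methylation, n_clones, seed) {
  if (any(true_methylation < 0 | true_methylation > 1)) {
    stop("methylation proportions must lie in [0, 1]")
  }
  stopifnot(n_clones >= 1)
  set.seed(as.integer(seed))
  m <- matrix(stats::rbinom(n_clones * length(true_methylation), 1,
                            rep(true_methylation, each = n_clones)),
              nrow = n_clones,
              dimnames = list(paste0("clone", seq_len(n_clones)),
                              paste0("cpg", seq_along(true_methylation))))
  m
}

#' Simulate a qPCR plate
#'
#' Emits replicate Ct values for one target and two reference assays (Actb,
#' Gapdh) per sample. The target's noiseless Ct equals the mean reference Ct
#' minus log2 of the sample's true relative expression, so the comparative
#' delta-delta-Ct method recovers planted folds exactly at zero noise.
#'
#' @param true_rel_expression named numeric vector: per-sample relative
#'   expression (control samples should be 1).
#' @param groups named character vector sample -> group.
#' @param ct_noise_sd replicate Ct noise standard deviation (cycles).
#' @param n_replicates technical replicates per assay (>= 3).
#' @param seed integer seed.
#' @param target assay name for the target gene.
#' @return long data.frame: sample, group, assay, replicate, ct.
#' @export
simulate_qpcr_plate <- function(true_rel_expression, groups, ct_noise_sd = 0.1,
                                n_replicates = 3, seed = 1, target = "target") {
  stopifnot(n_replicates >= 3)
  set.seed(as.integer(seed))
  ref_base <- c(Actb = 18, Gapdh = 20)
  samples <- names(true_rel_expression)
  rows <- list()
  for (s in samples) {
    base <- c(stats::setNames(mean(ref_base) - log2(true_rel_expression[[s]]), target),
              ref_base)
    for (a in names(base)) {
      rows[[length(rows) + 1]] <- data.frame(
        sample = s, group = groups[[s]], assay = a,
        replicate = seq_len(n_replicates),
        ct = base[[a]] + stats::rnorm(n_replicates, 0, ct_noise_sd),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
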