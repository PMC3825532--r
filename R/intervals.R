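#' Construct a genomic interval table
#'
#' Intervals are kept as plain data frames in 0-based half-open (BED)
#' coordinates throughout the package; conversion to the 1-based closed
#' convention of \pkg{GenomicRanges} happens only inside the helpers below.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end numeric vectors; 0-based half-open, so a 1 bp interval at
#'   position 100 is \code{start = 100, end = 101}.
#' @param ... further columns recycled alongside the coordinates.
#' @return data.frame with at least columns \code{chrom}, \code{start},
#'   \code{end}.
#' @export
intervals_df <- function(chrom, start, end, ...) {
  df <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end), ..., stringsAsFactors = FALSE)
  validate_intervals(df)
  df
}

validate_intervals <- function(df) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  if (nrow(df) == 0) return(invisible(df))
  bad <- which(!(df$start >= 0 & df$end > df$start))
  if (length(bad)) {
    stop("invalid interval(s) at row(s) ", paste(utils::head(bad, 5), collapse = ", "),
         ": require 0 <= start < end")
  }
  invisible(df)
}

# 0-based half-open data.frame -> GRanges (1-based closed)
as_granges0 <- function(df, seqlengths = NULL) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    seqlengths = seqlengths
  )
}

# GRanges -> 0-based half-open data.frame
from_granges0 <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Merge overlapping or book-ended intervals
#'
#' Per chromosome, intervals that overlap or touch (distance 0) are fused, as
#' \code{bedtools merge} does by default. The result is sorted and disjoint;
#' the operation is idempotent and independent of input order.
#'
#' @param regions interval data.frame (0-based half-open).
#' @return sorted, disjoint interval data.frame.
#' @export
merge_intervals <- function(regions) {
  validate_intervals(regions)
  if (nrow(regions) == 0) return(regions[, c("chrom", "start", "end")])
  gr <- GenomicRanges::reduce(as_granges0(regions))  # merges book-ended runs
  out <- from_granges0(gr)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Partition regions by feature overlap
#'
#' A region counts as overlapping when its intersection with any feature
#' interval is at least 1 bp (half-open arithmetic, so book-ended intervals do
#' not overlap).
#'
#' @param regions,features interval data.frames.
#' @return list with logical vector \code{overlaps} plus the two partitions
#'   \code{overlapping} and \code{non_overlapping}.
#' @export
classify_overlap <- function(regions, features) {
  validate_intervals(regions)
  validate_intervals(features)
  if (nrow(regions) == 0) {
    return(list(overlaps = logical(0), overlapping = regions, non_overlapping = regions))
  }
  ov <- if (nrow(features) == 0) {
    rep(FALSE, nrow(regions))
  } else {
    # disjoint sequence levels are an ordinary "no overlap", not a problem
    suppressWarnings(
      GenomicRanges::countOverlaps(as_granges0(regions), as_granges0(features),
                                   minoverlap = 1L)) > 0
  }
  list(overlaps = ov,
       overlapping = regions[ov, , drop = FALSE],
       non_overlapping = regions[!ov, , drop = FALSE])
}

#' Derive the feature catalog from a toy genome
#'
#' Builds the named interval sets used for overlap enrichment and gene-set
#' construction: CpG islands, gene bodies (TSS to transcript end), exons,
#' introns (gene body minus exons), strand-aware promoters (\code{promoter_bp}
#' upstream of the TSS, default 3 kb), 1-bp TSS intervals, and the non-genic
#' complement of gene bodies plus promoters. Genic sets carry a
#' \code{gene_id} column.
#'
#' @param genome a \code{toy_genome} (see \code{\link{generate_toy_genome}}) or
#'   a list with elements \code{chromosomes}, \code{genes}, \code{exons},
#'   \code{cgis} in the same layout.
#' @param promoter_bp promoter length upstream of the TSS in bp.
#' @param non_genic one of \code{"genes_and_promoters"} (default: complement of
#'   gene bodies union promoters) or \code{"genes_only"}.
#' @return named list of interval data.frames: \code{cgi}, \code{gene_body},
#'   \code{exon}, \code{intron}, \code{promoter}, \code{tss}, \code{non_genic}.
#' @export
feature_catalog <- function(genome, promoter_bp = 3000,
                            non_genic = c("genes_and_promoters", "genes_only")) {
  non_genic <- match.arg(non_genic)
  genes <- genome$genes
  exons <- genome$exons
  chrlen <- stats::setNames(genome$chromosomes$length, genome$chromosomes$name)

  gene_body <- data.frame(chrom = genes$chrom, start = genes$start, end = genes$end,
                          gene_id = genes$gene_id, stringsAsFactors = FALSE)

  plus <- genes$strand == "+"
  tss_pos <- ifelse(plus, genes$start, genes$end - 1)
  tss <- data.frame(chrom = genes$chrom, start = tss_pos, end = tss_pos + 1,
                    gene_id = genes$gene_id, stringsAsFactors = FALSE)

  prom_start <- ifelse(plus, pmax(0, genes$start - promoter_bp), genes$end)
  prom_end <- ifelse(plus, genes$start, pmin(chrlen[genes$chrom], genes$end + promoter_bp))
  keep <- prom_end > prom_start
  promoter <- data.frame(chrom = genes$chrom, start = prom_start, end = prom_end,
                         gene_id = genes$gene_id, stringsAsFactors = FALSE)[keep, , drop = FALSE]

  exon <- data.frame(chrom = exons$chrom, start = exons$start, end = exons$end,
                     gene_id = exons$gene_id, stringsAsFactors = FALSE)

  # introns: per gene, gene body minus its exons (genes are non-overlapping in
  # the toy genome, but compute per gene to stay general)
  intron_list <- lapply(split(seq_len(nrow(exons)), exons$gene_id), function(idx) {
    gid <- exons$gene_id[idx[1]]
    g <- genes[genes$gene_id == gid, , drop = FALSE]
    body <- IRanges::IRanges(g$start + 1, g$end)
    ex <- IRanges::IRanges(exons$start[idx] + 1, exons$end[idx])
    ir <- IRanges::setdiff(body, ex)
    if (length(ir) == 0) return(NULL)
    data.frame(chrom = g$chrom, start = IRanges::start(ir) - 1, end = IRanges::end(ir),
               gene_id = gid, stringsAsFactors = FALSE)
  })
  intron <- do.call(rbind, intron_list)
  if (is.null(intron)) {
    intron <- data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
                         gene_id = character(0), stringsAsFactors = FALSE)
  }
  rownames(intron) <- NULL

  genic <- if (non_genic == "genes_and_promoters") {
    rbind(gene_body[, 1:3], promoter[, 1:3])
  } else {
    gene_body[, 1:3]
  }
  ng <- complement_intervals(genic, genome$chromosomes)

  list(cgi = genome$cgis[, c("chrom", "start", "end")],
       gene_body = gene_body, exon = exon, intron = intron,
       promoter = promoter, tss = tss, non_genic = ng)
}

#' Complement of an interval set within chromosome bounds
#'
#' @param regions interval data.frame.
#' @param chromosomes data.frame with columns \code{name}, \code{length}.
#' @return interval data.frame covering every bp not in \code{regions}.
#' @export
complement_intervals <- function(regions, chromosomes) {
  out <- lapply(seq_len(nrow(chromosomes)), function(i) {
    nm <- chromosomes$name[i]
    L <- chromosomes$length[i]
    sub <- regions[regions$chrom == nm, , drop = FALSE]
    if (nrow(sub) == 0) {
      return(data.frame(chrom = nm, start = 0, end = L, stringsAsFactors = FALSE))
    }
    ir <- IRanges::reduce(IRanges::IRanges(sub$start + 1, pmin(sub$end, L)))
    gaps <- IRanges::gaps(ir, start = 1, end = L)
    if (length(gaps) == 0) return(NULL)
    data.frame(chrom = nm, start = IRanges::start(gaps) - 1, end = IRanges::end(gaps),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) out <- data.frame(chrom = character(0), start = numeric(0), end = numeric(0))
  rownames(out) <- NULL
  out
}
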