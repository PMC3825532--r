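#' Remove duplicate tags
#'
#' Keeps at most one tag per (sample, chrom, 5' position, strand), mirroring
#' the removal of PCR duplicates that align to the same location in the same
#' sample. The result is independent of input order.
#'
#' @param tags data.frame with columns chrom, pos5, strand, sample.
#' @return deduplicated tag data.frame (original attributes preserved).
#' @export
deduplicate_tags <- function(tags) {
  key <- paste(tags$sample, tags$chrom, tags$pos5, tags$strand, sep = "\r")
  out <- tags[!duplicated(key), , drop = FALSE]
  out <- out[order(out$sample, out$chrom, out$pos5, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "groups") <- attr(tags, "groups")
  out
}

# shifted fragment-center position of each tag: + strand tags move downstream
# by `shift`, - strand tags upstream; clamped to [0, chrom length - 1]
shift_positions <- function(tags, chrom_lengths, shift = 75) {
  stopifnot(shift >= 0)
  pos <- ifelse(tags$strand == "+", tags$pos5 + shift, tags$pos5 - shift)
  pmin(pmax(pos, 0), chrom_lengths[tags$chrom] - 1)
}

#' Shift tags and pile into per-bp mass
#'
#' Each tag contributes unit mass at its shifted 5' position (see
#' \code{shift_positions}); positions falling outside the chromosome are
#' clamped to its bounds.
#'
#' @param tags tag data.frame.
#' @param chrom_lengths named vector of chromosome lengths.
#' @param shift fixed shift size in bp (default 75, half the assumed fragment).
#' @return data.frame chrom, pos, count (positions with mass only).
#' @export
shift_and_pile <- function(tags, chrom_lengths, shift = 75) {
  pos <- shift_positions(tags, chrom_lengths, shift)
  agg <- stats::aggregate(list(count = rep(1L, length(pos))),
                          by = list(chrom = tags$chrom, pos = pos), FUN = sum)
  agg <- agg[order(agg$chrom, agg$pos), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Call enriched windows of one sample against another
#'
#' A simplified fixed-shift Poisson window caller: tags of both samples are
#' shifted by \code{shift} bp toward the fragment center, a window of width
#' \code{window} slides along each chromosome in steps of \code{step} bp, and
#' a window is significant when the upper-tail Poisson probability of the
#' treatment count is below \code{p_cutoff} under rate
#' \code{lambda = max(genome-wide control rate, local control rate in a
#' `local_bg` bp neighbourhood) * window * library-size ratio}. Overlapping or
#' book-ended significant windows are fused into one region carrying the
#' minimum window p value.
#'
#' @param treatment_tags,control_tags deduplicated tag data.frames (single
#'   sample each).
#' @param chrom_lengths named vector of chromosome lengths.
#' @param shift fixed shift in bp.
#' @param window window width (default twice the shift).
#' @param p_cutoff Poisson significance cutoff (default 1e-5).
#' @param step window step in bp.
#' @param local_bg width of the local background neighbourhood in bp.
#' @return interval data.frame with column \code{peak_p}.
#' @export
call_enriched_windows <- function(treatment_tags, control_tags, chrom_lengths,
                                  shift = 75, window = 2 * shift,
                                  p_cutoff = 1e-5, step = 10,
                                  local_bg = 10000) {
  if (nrow(control_tags) == 0) stop("empty control sample: no background estimable")
  n_t <- nrow(treatment_tags)
  n_c <- nrow(control_tags)
  ratio <- n_t / n_c
  genome_len <- sum(chrom_lengths)
  global_rate <- n_c / genome_len

  pos_t <- split(shift_positions(treatment_tags, chrom_lengths, shift),
                 treatment_tags$chrom)
  pos_c <- split(shift_positions(control_tags, chrom_lengths, shift),
                 control_tags$chrom)
  out <- list()
  for (chrom in names(chrom_lengths)) {
    L <- chrom_lengths[[chrom]]
    pt <- sort(pos_t[[chrom]])
    if (is.null(pt) || length(pt) == 0) next
    pc <- sort(pos_c[[chrom]])
    if (is.null(pc)) pc <- numeric(0)
    starts <- seq(0, max(0, L - window), by = step)
    count_in <- function(p, lo, hi) {  # tags with lo <= pos < hi
      findInterval(hi - 0.5, p) - findInterval(lo - 0.5, p)
    }
    ct <- count_in(pt, starts, starts + window)
    cand <- which(ct > 0)
    if (length(cand) == 0) next
    s <- starts[cand]
    centre <- s + window / 2
    loc_lo <- pmax(0, centre - local_bg / 2)
    loc_hi <- pmin(L, centre + local_bg / 2)
    cc_local <- count_in(pc, loc_lo, loc_hi)
    local_rate <- cc_local / (loc_hi - loc_lo)
    lambda <- pmax(global_rate, local_rate) * window * ratio
    p <- stats::ppois(ct[cand] - 1, lambda, lower.tail = FALSE)
    sig <- p < p_cutoff
    if (!any(sig)) next
    s <- s[sig]; p <- p[sig]
    # fuse runs of overlapping/book-ended significant windows
    grp <- cumsum(c(TRUE, s[-1] - s[-length(s)] > window))
    out[[chrom]] <- data.frame(
      chrom = chrom,
      start = as.numeric(tapply(s, grp, min)),
      end = as.numeric(tapply(s, grp, max)) + window,
      peak_p = as.numeric(tapply(p, grp, min)),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
                      peak_p = numeric(0))
  }
  rownames(res) <- NULL
  res
}

#' Candidate regions from all ordered pairwise comparisons
#'
#' Runs \code{\link{call_enriched_windows}} for every ordered pair of samples
#' (both directions, so methylation gains and losses are both discoverable)
#' and accumulates the enriched regions.
#'
#' @param tags deduplicated multi-sample tag data.frame.
#' @param chrom_lengths named vector of chromosome lengths.
#' @param ... passed to \code{\link{call_enriched_windows}}.
#' @return interval data.frame with columns treatment, control, peak_p; the
#'   number of comparisons run is attached as attribute \code{n_comparisons}.
#' @export
pairwise_candidate_regions <- function(tags, chrom_lengths, ...) {
  samples <- unique(tags$sample)
  if (length(samples) < 2) stop("need >= 2 samples for pairwise comparison")
  by_sample <- split(tags, tags$sample)
  out <- list()
  n_cmp <- 0
  for (trt in samples) for (ctl in samples) {
    if (trt == ctl) next
    n_cmp <- n_cmp + 1
    r <- call_enriched_windows(by_sample[[trt]], by_sample[[ctl]],
                               chrom_lengths, ...)
    if (nrow(r) > 0) {
      r$treatment <- trt
      r$control <- ctl
      out[[length(out) + 1]] <- r
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
                      peak_p = numeric(0), treatment = character(0),
                      control = character(0))
  }
  rownames(res) <- NULL
  attr(res, "n_comparisons") <- n_cmp
  res
}
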