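# shared fixture builders and brute-force oracles

tiny_genome <- function(seed = 42) {
  generate_toy_genome(n_chroms = 2, chrom_length = 5e5, n_genes = 20,
                      n_cgis = 30, seed = seed)
}

make_tags <- function(chrom, pos5, strand = "+", sample = "s1") {
  data.frame(chrom = chrom, pos5 = pos5, strand = strand, sample = sample,
             stringsAsFactors = FALSE)
}

random_intervals <- function(n, chroms = c("chr1", "chr2"), max_pos = 1e4, seed = 1) {
  set.seed(seed)
  start <- sample.int(max_pos, n, replace = TRUE)
  len <- sample.int(200, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE), start = start,
             end = start + len, stringsAsFactors = FALSE)
}

# brute-force interval union via a per-bp occupancy vector
oracle_merge <- function(df, max_pos = 2e4) {
  out <- lapply(split(df, df$chrom), function(sub) {
    occ <- logical(max_pos)
    for (i in seq_len(nrow(sub))) {
      occ[(sub$start[i] + 1):sub$end[i]] <- TRUE
    }
    r <- rle(occ)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    keep <- r$values
    if (!any(keep)) return(NULL)
    data.frame(chrom = sub$chrom[1], start = starts[keep] - 1, end = ends[keep],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$chrom, out$start), , drop = FALSE]
}

# brute-force all-pairs overlap (>= 1 bp, half-open)
oracle_overlaps <- function(regions, features) {
  vapply(seq_len(nrow(regions)), function(i) {
    any(features$chrom == regions$chrom[i] &
          pmin(features$end, regions$end[i]) - pmax(features$start, regions$start[i]) >= 1)
  }, logical(1))
}

# null count matrix: no group effect
null_count_matrix <- function(n_rows, n_per_group = c(4, 5), mu = 60,
                              phi = 0.1, seed = 1) {
  set.seed(seed)
  n <- sum(n_per_group)
  m <- matrix(rnbinom(n_rows * n, size = 1 / phi, mu = mu), n_rows, n,
              dimnames = list(paste0("r", seq_len(n_rows)),
                              paste0("s", seq_len(n))))
  attr(m, "groups") <- setNames(rep(c("A", "B"), n_per_group), colnames(m))
  m
}
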