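#' Read genomic intervals from a BED or gene-table file
#'
#' Coordinates are returned 0-based half-open regardless of dialect. The BED
#' dialect expects at least chrom/start/end; optional columns 4-6 are kept as
#' \code{name}, \code{score}, \code{strand}. The gene-table dialect is the
#' tab-separated layout written by \code{\link{write_gene_table}}:
#' \code{gene_id chrom start end strand exon_starts exon_ends} with
#' comma-separated exon blocks.
#'
#' @param path file path.
#' @param dialect "bed" or "gene-table".
#' @return for BED, an interval data.frame; for gene-table, a list with
#'   \code{genes} and \code{exons} data.frames.
#' @export
read_intervals <- function(path, dialect = c("bed", "gene-table")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines)]
  if (length(lines) == 0 || all(!nzchar(lines))) {
    warning("empty interval file: ", path)
    if (dialect == "bed") {
      return(data.frame(chrom = character(0), start = numeric(0), end = numeric(0)))
    }
    return(list(genes = data.frame(), exons = data.frame()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (dialect == "bed") {
    parse_bed_fields(fields, path)
  } else {
    parse_gene_table_fields(fields, path)
  }
}

parse_bed_fields <- function(fields, path) {
  n <- lengths(fields)
  if (any(n < 3)) {
    stop("malformed BED line ", which(n < 3)[1], " in ", path, ": fewer than 3 fields")
  }
  chrom <- vapply(fields, `[`, character(1), 1)
  start <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 2)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 3)))
  bad <- which(is.na(start) | is.na(end) | start < 0 | end <= start)
  if (length(bad)) {
    stop("malformed BED line ", bad[1], " in ", path,
         ": require numeric 0 <= start < end")
  }
  df <- data.frame(chrom = chrom, start = start, end = end, stringsAsFactors = FALSE)
  if (all(n >= 4)) df$name <- vapply(fields, `[`, character(1), 4)
  if (all(n >= 5)) df$score <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 5)))
  if (all(n >= 6)) df$strand <- vapply(fields, `[`, character(1), 6)
  df
}

parse_gene_table_fields <- function(fields, path) {
  n <- lengths(fields)
  if (any(n != 7)) {
    stop("malformed gene-table line ", which(n != 7)[1], " in ", path,
         ": expected 7 tab-separated fields")
  }
  col <- function(i) vapply(fields, `[`, character(1), i)
  genes <- data.frame(gene_id = col(1), chrom = col(2),
                      start = as.numeric(col(3)), end = as.numeric(col(4)),
                      strand = col(5), stringsAsFactors = FALSE)
  bad <- which(is.na(genes$start) | is.na(genes$end) | genes$start < 0 |
                 genes$end <= genes$start | !genes$strand %in% c("+", "-"))
  if (length(bad)) stop("malformed gene-table line ", bad[1], " in ", path)
  ex <- lapply(seq_along(fields), function(i) {
    s <- as.numeric(strsplit(col(6)[i], ",", fixed = TRUE)[[1]])
    e <- as.numeric(strsplit(col(7)[i], ",", fixed = TRUE)[[1]])
    if (length(s) != length(e) || any(is.na(s)) || any(is.na(e)) || any(e <= s)) {
      stop("malformed exon blocks at gene-table line ", i, " in ", path)
    }
    data.frame(gene_id = genes$gene_id[i], chrom = genes$chrom[i],
               start = s, end = e, stringsAsFactors = FALSE)
  })
  list(genes = genes, exons = do.call(rbind, ex))
}

#' Write intervals as BED
#'
#' @param df interval data.frame; optional \code{name}, \code{score},
#'   \code{strand} columns fill BED columns 4-6.
#' @param path output path.
#' @export
write_intervals <- function(df, path) {
  validate_intervals(df)
  cols <- list(df$chrom, format(df$start, scientific = FALSE, trim = TRUE),
               format(df$end, scientific = FALSE, trim = TRUE))
  if (!is.null(df$name)) {
    cols <- c(cols, list(df$name,
                         if (is.null(df$score)) rep(0, nrow(df)) else df$score,
                         if (is.null(df$strand)) rep(".", nrow(df)) else df$strand))
  }
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}

#' Write a gene annotation table
#'
#' Tab-separated: gene_id, chrom, start, end, strand, comma-joined exon starts
#' and ends (0-based half-open).
#' @param genes,exons data.frames as in a toy genome.
#' @param path output path.
#' @export
write_gene_table <- function(genes, exons, path) {
  lines <- vapply(seq_len(nrow(genes)), function(i) {
    ex <- exons[exons$gene_id == genes$gene_id[i], , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    paste(genes$gene_id[i], genes$chrom[i],
          format(genes$start[i], scientific = FALSE, trim = TRUE),
          format(genes$end[i], scientific = FALSE, trim = TRUE),
          genes$strand[i],
          paste(format(ex$start, scientific = FALSE, trim = TRUE), collapse = ","),
          paste(format(ex$end, scientific = FALSE, trim = TRUE), collapse = ","),
          sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a count matrix from TSV
#'
#' First column holds row identifiers; the header row holds sample labels.
#' Counts must be nonnegative integers and row identifiers unique.
#'
#' @param path TSV file.
#' @return integer matrix with row and column names.
#' @export
read_count_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) {
    stop("duplicate row identifier: ", ids[duplicated(ids)][1])
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m) || any(is.na(m)) || any(m < 0) || any(m != round(m))) {
    stop("counts must be nonnegative integers")
  }
  storage.mode(m) <- "integer"
  rownames(m) <- ids
  m
}

#' Write a count matrix as TSV
#' @param m matrix with row and column names.
#' @param path output path.
#' @param id_col header for the identifier column.
#' @export
write_count_matrix <- function(m, path, id_col = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read tag alignments from 6-column BED
#'
#' Column 4 carries the sample label; the tag's 5' position is the BED start
#' for + strand tags and end - 1 for - strand tags.
#'
#' @param path BED file.
#' @return data.frame with columns chrom, pos5, strand, sample.
#' @export
read_tag_bed <- function(path) {
  df <- read_intervals(path, "bed")
  if (is.null(df$strand) || is.null(df$name)) {
    stop("tag BED requires 6 columns (name = sample, strand)")
  }
  data.frame(chrom = df$chrom,
             pos5 = ifelse(df$strand == "+", df$start, df$end - 1),
             strand = df$strand, sample = df$name, stringsAsFactors = FALSE)
}

#' Write tag alignments as 6-column BED
#' @param tags tag data.frame (chrom, pos5, strand, sample).
#' @param path output path.
#' @param read_length tag length used to fill the BED end coordinate.
#' @export
write_tag_bed <- function(tags, path, read_length = 36) {
  start <- ifelse(tags$strand == "+", tags$pos5, pmax(0, tags$pos5 - read_length + 1))
  end <- ifelse(tags$strand == "+", tags$pos5 + read_length, tags$pos5 + 1)
  df <- data.frame(chrom = tags$chrom, start = start, end = end,
                   name = tags$sample, score = 0, strand = tags$strand)
  write_intervals(df, path)
}

#' Read/write gene sets in GMT-like format
#'
#' Tab-separated lines: set name, description, then member ids.
#' @param path file path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- vapply(fields, `[`, character(1), 1)
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @param descriptions optional character vector of descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a simulation/pipeline configuration from a YAML file
#'
#' A flat key-value file; \code{seed} is mandatory.
#' @param path YAML file.
#' @return named list.
#' @export
read_config_file <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$seed)) stop("config must set a seed")
  cfg
}
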