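#!/usr/bin/env Rscript
# Differential methylation and expression: count tags per merged region,
# drop the weakest half of regions (50th-centile sum filter; 30th for
# expression), TMM-normalize, test with the shrunken NB exact test, adjust
# with BH, and cluster the significant profiles.
suppressMessages(library(dmrcap))

sim <- "results/simulated"
chrlen <- c(chr1 = 2e6, chr2 = 2e6, chr3 = 2e6)
tags <- deduplicate_tags({
  t <- read_tag_bed("scratch/simulated/tags.bed")
  attr(t, "groups") <- unlist(read_config_file(file.path(sim, "config.yaml"))$groups)
  t
})
regions <- read_intervals("results/candidate_regions.bed", "bed")

mat <- count_tags_per_region(regions, tags, chrlen, shift = 75)
mat <- centile_filter(mat, 50)
grp <- factor(attr(tags, "groups")[colnames(mat)], levels = c("CTRL", "PILO"))
nf <- tmm_factors(mat)
disp <- estimate_dispersions(mat, grp, nf, prior_df = 10)
dmr <- nb_exact_test(mat, grp, disp, nf)
write.table(dmr, "results/dmr_table.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

expr <- read_count_matrix(file.path(sim, "expression_counts.tsv"))
egrp <- factor(sub("_.*", "", colnames(expr)), levels = c("CTRL", "PILO"))
emat <- centile_filter(expr, 30)
ede <- nb_exact_test(emat, egrp)
write.table(ede, "results/expression_de.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat("regions tested:", nrow(mat), "| DMRs p<0.01:", sum(dmr$p < 0.01),
    "(", sum(dmr$p < 0.01 & dmr$logFC > 0), "hyper /",
    sum(dmr$p < 0.01 & dmr$logFC < 0), "hypo )\n")
cat("genes tested:", nrow(emat), "| DE p<0.01:", sum(ede$p < 0.01), "\n")
cat("common dispersion:", signif(disp$common, 3), "\n")

# heat-map style clustering of significant regions (z-scored log-CPM)
sig <- dmr$id[dmr$p < 0.01]
if (length(sig) >= 2) {
  eff <- colSums(mat) * nf
  logcpm <- log2(sweep(mat[sig, , drop = FALSE] + 0.5, 2, eff / 1e6, `/`))
  cl <- zscore_cluster(logcpm)
  top <- cutree(cl$col_hclust, k = 2)
  cat("column dendrogram top split:",
      paste(names(top), top, sep = ":", collapse = " "), "\n")
  writeLines(cl$col_order, "results/cluster_column_order.txt")
}
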